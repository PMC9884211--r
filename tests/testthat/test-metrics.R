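star_network <- function() {
  ids <- c("hub", paste0("leaf", 1:4))
  w <- matrix(0, 5, 5, dimnames = list(ids, ids))
  w["hub", ] <- 0.5; w[, "hub"] <- 0.5; diag(w) <- 0
  w
}

test_that("strength sums absolute incident weights", {
  ids <- c("a", "b", "c")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 0.3
  w["a", "c"] <- w["c", "a"] <- -0.2
  s <- node_strength(w)
  expect_equal(s$strength[s$item == "a"], 0.5)
  expect_equal(s$strength[s$item == "b"], 0.3)
  # sign flip leaves strength unchanged
  expect_equal(node_strength(-w)$strength, s$strength)
  # isolated node
  w0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  w0["x", "y"] <- w0["y", "x"] <- 0.4
  w3 <- rbind(cbind(w0, z = 0), z = 0)
  colnames(w3) <- rownames(w3) <- c("x", "y", "z")
  expect_equal(node_strength(w3)$strength[3], 0)
})

test_that("expected influence keeps signs and propagates two steps", {
  ids <- c("a", "b", "c")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 0.3
  w["a", "c"] <- w["c", "a"] <- -0.2
  e1 <- expected_influence(w, 1)
  expect_equal(e1$ei[e1$item == "a"], 0.1)

  # all-positive network: EI1 equals strength
  wp <- abs(w)
  expect_equal(expected_influence(wp, 1)$ei, node_strength(wp)$strength)

  # 4-leaf star with weights 0.5: leaf EI2 = 0.5 + 0.5 * 2.0 = 1.5
  ws <- star_network()
  e2 <- expected_influence(ws, 2)
  expect_equal(e2$ei[e2$item == "leaf1"], 1.5)
  # hub EI2 = 2 + 4 * (0.5 * 0.5) = 3
  expect_equal(e2$ei[e2$item == "hub"], 3)
  expect_error(expected_influence(w, 3), "steps")
})

test_that("EI1 never exceeds strength, with equality iff no negative edges", {
  set.seed(15)
  for (i in 1:10) {
    w <- random_corr(6) * 0.4; diag(w) <- 0
    dimnames(w) <- list(letters[1:6], letters[1:6])
    s <- node_strength(w)$strength
    e <- expected_influence(w, 1)$ei
    expect_true(all(e <= s + 1e-12))
    pos_rows <- apply(w >= 0, 1, all)
    expect_equal(e[pos_rows], s[pos_rows])
  }
})

test_that("network loadings decompose strength and standardize per dimension", {
  ids <- c("a", "b", "c", "d")
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 0.4
  part <- stats::setNames(c(1L, 1L, 2L, 2L), ids)
  nl <- network_loadings(w, part)
  expect_equal(nl$raw["a", "1"], 0.4)
  expect_equal(nl$raw["a", "2"], 0)
  expect_equal(nl$raw["c", ], c(`1` = 0, `2` = 0))  # isolated: zero row

  # conservation: rowSums of raw loadings = strength, on random networks
  set.seed(16)
  for (i in 1:5) {
    wr <- random_corr(8) * 0.3; diag(wr) <- 0
    dimnames(wr) <- list(letters[1:8], letters[1:8])
    pr <- stats::setNames(sample(1:3, 8, TRUE), letters[1:8])
    pr[1:3] <- 1:3   # keep all three communities occupied
    nlr <- network_loadings(wr, pr)
    expect_equal(unname(rowSums(nlr$raw)), node_strength(wr)$strength)
  }
})

test_that("cross-loadings are small relative to main loadings on easy data", {
  g <- easy_synth(seed = 29, n = 1000, factors = 2, items = 5)
  net <- network_from_data(g$data, method = "pearson")
  nl <- network_loadings(net, g$partition)
  lab <- g$partition$assignment[rownames(nl$standardized)]
  main <- nl$standardized[cbind(seq_along(lab), lab)]
  cross <- nl$standardized[cbind(seq_along(lab), 3 - lab)]
  expect_lt(mean(cross) / mean(main), 0.25)
})

test_that("top/bottom ranking is deterministic with id tie-breaks", {
  tb <- tibble::tibble(item = c("a", "b", "c", "d"),
                       strength = c(3, 1, 2, 4))
  got <- top_bottom_nodes(tb, k = 2)
  expect_equal(got$top$item, c("d", "a"))
  expect_equal(got$bottom$item, c("b", "c"))
  # ties broken by item id
  tie <- tibble::tibble(item = c("b", "a", "c"), strength = c(1, 1, 1))
  expect_equal(top_bottom_nodes(tie, k = 2)$top$item, c("a", "b"))
  expect_error(top_bottom_nodes(tb, k = 9), "exceeds")
})

test_that("subscale agreement reports missing and foreign items", {
  key <- item_key(
    subscales = list(F1 = c("1", "2", "3"), F2 = c("4", "5", "6")),
    composites = list(C = c("F1", "F2")),
    items = as.character(1:7), allowed_subscales = NULL)
  # partition identical to the subscale structure
  perfect <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 1L),
                             as.character(1:7))
  ag <- subscale_agreement(perfect, key)
  expect_equal(ag$missing_items, c("", ""))
  expect_equal(ag$foreign_items, c("", ""))
  expect_setequal(ag$subscales, c("F1", "F2"))
  expect_equal(attr(ag, "unscored")$item, "7")

  # item 3 defects to the F2 community
  moved <- stats::setNames(c(1L, 1L, 2L, 2L, 2L, 2L, 2L),
                           as.character(1:7))
  ag2 <- subscale_agreement(moved, key)
  f1 <- ag2[ag2$subscales == "F1", ]
  f2 <- ag2[ag2$subscales == "F2", ]
  expect_match(f1$missing_items, "3 \\(F1\\)")
  expect_match(f2$foreign_items, "3 \\(F1\\)")

  # invariance to label permutation (community numbers aside)
  perm <- stats::setNames(c(2L, 2L, 2L, 1L, 1L, 1L, 2L),
                          as.character(1:7))
  ag3 <- subscale_agreement(perm, key)
  pick <- function(a) dplyr::arrange(
    tibble::tibble(subscales = a$subscales, missing = a$missing_items,
                   foreign = a$foreign_items, composite = a$composite,
                   n_items = a$n_items), subscales)
  expect_equal(pick(ag3), pick(ag))
})
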