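test_that("weighted topological overlap matches hand-computed cases", {
  ids2 <- c("a", "b")
  w <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(ids2, ids2))
  # single edge 0.5: omega = 0.5 / (0.5 + 1 - 0.5) = 0.5
  expect_equal(wto(w)["a", "b"], 0.5)

  ids3 <- c("a", "b", "c")
  tri <- matrix(1, 3, 3, dimnames = list(ids3, ids3)); diag(tri) <- 0
  # unit triangle: omega = (1 + 1) / (2 + 1 - 1) = 1 for every pair
  om <- wto(tri)
  expect_equal(om[upper.tri(om)], rep(1, 3))

  empty <- matrix(0, 3, 3, dimnames = list(ids3, ids3))
  expect_equal(max(abs(wto(empty))), 0)
  expect_error(wto(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("wto is symmetric and invariant to a global sign flip", {
  set.seed(3)
  w <- random_corr(8) * 0.3; diag(w) <- 0
  dimnames(w) <- list(letters[1:8], letters[1:8])
  om <- wto(w)
  expect_equal(om, t(om))
  expect_equal(wto(-w), om)
  expect_true(all(om >= 0))
})

test_that("overlap p-values rank pairs and match the gamma tail", {
  # exchangeability (empirical family: equal overlaps get equal p)
  ids <- letters[1:6]
  om <- matrix(0.2, 6, 6, dimnames = list(ids, ids)); diag(om) <- 0
  pv <- redundancy_pvalues(om, family = "empirical")
  expect_equal(length(unique(pv$p)), 1)
  # zero-variance overlaps break the parametric fit explicitly
  expect_error(redundancy_pvalues(om, family = "gamma"), "zero variance")

  # the largest overlap gets the smallest p
  set.seed(4)
  net <- abs(random_corr(8)) * 0.3; diag(net) <- 0
  dimnames(net) <- list(letters[1:8], letters[1:8])
  om2 <- wto(net)
  pv2 <- redundancy_pvalues(om2, family = "gamma")
  expect_equal(pv2$p[which.max(pv2$omega)], min(pv2$p))

  # method-of-moments gamma fit converges to the true tail probability
  set.seed(5)
  p <- 101
  ids <- as.character(seq_len(p))
  m <- matrix(0, p, p, dimnames = list(ids, ids))
  m[upper.tri(m)] <- rgamma(p * (p - 1) / 2, shape = 2, scale = 0.1)
  m <- m + t(m)
  m["1", "2"] <- m["2", "1"] <- 0.9
  pv3 <- redundancy_pvalues(m, family = "gamma")
  got <- pv3$p[pv3$item_i == "1" & pv3$item_j == "2"]
  expect_lt(abs(got - pgamma(0.9, 2, scale = 0.1, lower.tail = FALSE)), 1e-3)

  expect_error(redundancy_pvalues(diag(3) * 0), "too few")
})

test_that("adaptive alpha reduces to the base level at the reference size", {
  expect_equal(adaptive_alpha(10, base_alpha = 0.05, n_ref = 10), 0.05)
  expect_lt(adaptive_alpha(1000, base_alpha = 0.05, n_ref = 10), 0.05)
  # direct evaluation of the formula
  q <- qchisq(0.95, df = 1)
  expect_equal(adaptive_alpha(1000, 0.05, 10),
               0.05 * sqrt(10 * (log(10) + q)) / sqrt(1000 * (log(1000) + q)))
  # decreasing in the number of tests
  a <- vapply(c(10, 50, 200, 1000), adaptive_alpha, numeric(1))
  expect_true(all(diff(a) < 0))
  expect_error(adaptive_alpha(0), "n_tests")
})

test_that("merge sets follow the direct-connection / clique heuristic", {
  omega_for <- function(ids, boost = NULL) {
    m <- matrix(0.1, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 0
    if (!is.null(boost)) m[boost, ] <- m[, boost] <- 0.5
    diag(m) <- 0
    m
  }
  # single significant pair
  p1 <- tibble::tibble(item_i = "a", item_j = "b")
  ms1 <- build_merge_sets(p1, omega_for(c("a", "b")))
  expect_equal(ms1$merge_sets, list(c("a", "b")))

  # chain a-b-c, target b (largest summed overlap): all three merge
  p2 <- tibble::tibble(item_i = c("a", "b"), item_j = c("b", "c"))
  ms2 <- build_merge_sets(p2, omega_for(c("a", "b", "c"), boost = "b"))
  expect_equal(ms2$merge_sets, list(c("a", "b", "c")))

  # path a-b-c-d, target b: d is not adjacent to b and defers
  p3 <- tibble::tibble(item_i = c("a", "b", "c"), item_j = c("b", "c", "d"))
  ms3 <- build_merge_sets(p3, omega_for(c("a", "b", "c", "d"), boost = "b"))
  expect_equal(ms3$merge_sets, list(c("a", "b", "c")))
  expect_equal(ms3$chains, list(`1` = c("a", "b", "c", "d")))

  expect_equal(build_merge_sets(NULL, NULL)$merge_sets, list())
})

test_that("merging produces faithful composite scores", {
  set.seed(6)
  z <- rnorm(400)
  d <- tibble::tibble(a = as.integer(cut(z, c(-Inf, -1, 0, 1, Inf))) - 1L,
                      c = sample(0:3, 400, TRUE))
  d$b <- d$a
  # two perfectly correlated items: latent score correlates 1 with either
  m <- merge_items(d, list(c("a", "b")), method = "latent")
  expect_named(m, c("a_b", "c"))
  expect_equal(abs(cor(m$a_b, d$a)), 1, tolerance = 1e-10)

  # sum method: items (0, 4) average to 2
  d2 <- tibble::tibble(x = 0L, y = 4L, z = 1L)
  m2 <- merge_items(d2, list(c("x", "y")), method = "sum")
  expect_equal(m2$x_y, 2)

  expect_error(merge_items(d, list(c("a", "b"), c("b", "c"))), "disjoint")
  expect_error(merge_items(d, list(c("a", "q"))), "unknown item")
})

test_that("a one-factor fit recovers planted loadings on merged sets", {
  set.seed(8)
  n <- 4000
  f <- rnorm(n)
  lam <- c(0.9, 0.8, 0.7)
  x <- vapply(lam, function(l) l * f + rnorm(n, sd = sqrt(1 - l^2)),
              numeric(n))
  fit <- factanal(covmat = cor(x), factors = 1, n.obs = n)
  expect_lt(max(abs(as.numeric(fit$loadings) - lam)), 0.05)
})

test_that("run_uva merges exactly the planted clone and nothing else", {
  g <- easy_synth(seed = 11, n = 500, factors = 3, items = 5)
  d <- inject_redundancy(g$data, c("3" = 0.15), seed = 99)
  u <- run_uva(d)
  expect_equal(u$report$merge_map, list(`3_3r` = c("3", "3r")))
  expect_setequal(names(u$data), c(setdiff(names(g$data), "3"), "3_3r"))

  # independence data: zero merges, output identical to input
  ind <- generate_factor_data(synth_spec(n_respondents = 500, n_factors = 3,
                                         items_per_factor = 5, loading = 0,
                                         factor_corr = 0, seed = 5))
  u2 <- run_uva(ind$data)
  expect_length(u2$report$merge_map, 0)
  expect_identical(as.data.frame(u2$data), as.data.frame(ind$data))

  # idempotence: a second pass on converged output merges nothing
  u3 <- run_uva(u$data)
  expect_length(u3$report$merge_map, 0)
})
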