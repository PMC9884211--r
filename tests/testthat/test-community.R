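clique_pair <- function(weight = 0.5, bridge = 0) {
  ids <- letters[1:8]
  w <- matrix(0, 8, 8, dimnames = list(ids, ids))
  w[1:4, 1:4] <- weight
  w[5:8, 5:8] <- weight
  diag(w) <- 0
  if (bridge != 0) w[4, 5] <- w[5, 4] <- bridge
  w
}

test_that("spinglass separates two cliques and keeps one clique together", {
  # two 4-cliques joined by one positive edge (connected graph)
  w <- clique_pair(bridge = 0.05)
  p <- spinglass_partition(w, seed = 1, restarts = 5)
  lab <- p$assignment
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  # and the solution attains the exhaustive optimum
  expect_equal(p$energy, exhaustive_min_energy(w), tolerance = 1e-10)

  one <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(one) <- 0
  p1 <- spinglass_partition(one, seed = 1, restarts = 5)
  expect_equal(length(unique(p1$assignment)), 1)

  expect_error(spinglass_partition(matrix(0, 3, 3), seed = 1),
               "no structure")
})

test_that("a negative bridge keeps cliques apart across seeds", {
  w <- clique_pair(bridge = -0.5)
  for (s in 1:20) {
    p <- spinglass_partition(w, seed = s, restarts = 1)
    expect_false(any(p$assignment[1:4] %in% p$assignment[5:8]))
  }
})

test_that("best-of-restarts attains the exhaustive Hamiltonian optimum", {
  set.seed(9)
  for (i in 1:3) {
    # random signed connected network on 7 nodes
    ids <- letters[1:7]
    w <- matrix(0, 7, 7, dimnames = list(ids, ids))
    w[upper.tri(w)] <- sample(c(0, 0.4, -0.3), 21, TRUE, c(0.3, 0.5, 0.2))
    w[1, 2:7] <- abs(w[1, 2:7]) + 0.1  # guarantee connectivity via node 1
    w <- w + t(w)
    p <- spinglass_partition(w, seed = i, restarts = 20)
    expect_equal(p$energy, exhaustive_min_energy(w), tolerance = 1e-10)
  }
})

test_that("spinglass is deterministic given the seed", {
  g <- easy_synth(seed = 7, n = 400, factors = 2, items = 4)
  net <- network_from_data(g$data, method = "pearson")
  a <- spinglass_partition(net, seed = 3, restarts = 3)
  b <- spinglass_partition(net, seed = 3, restarts = 3)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$energy, b$energy)
})

test_that("NMI and AMI obey their identities", {
  pa <- stats::setNames(c(1, 1, 2, 2), letters[1:4])
  pb <- stats::setNames(c(2, 2, 1, 1), letters[1:4])
  pc <- stats::setNames(c(1, 2, 1, 2), letters[1:4])
  expect_equal(nmi(pa, pa), 1)
  expect_equal(nmi(pa, pb), 1)     # label invariance
  expect_equal(ami(pa, pa), 1)
  expect_equal(ami(pa, pb), 1)
  # symmetry
  expect_equal(nmi(pa, pc), nmi(pc, pa))
  expect_equal(ami(pa, pc), ami(pc, pa))
  # both-single-cluster convention
  ones <- stats::setNames(c(1, 1, 1), letters[1:3])
  expect_equal(nmi(ones, ones), 1)
  # node-set mismatch
  expect_error(nmi(pa, ones), "different node sets")
})

test_that("authored NMI matches igraph's arithmetic-normalized NMI", {
  set.seed(10)
  for (i in 1:20) {
    x <- sample(1:4, 50, TRUE)
    y <- sample(1:3, 50, TRUE)
    nx <- stats::setNames(x, paste0("n", 1:50))
    ny <- stats::setNames(y, paste0("n", 1:50))
    expect_equal(nmi(nx, ny), igraph::compare(x, y, method = "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("AMI is centered at zero for independent partitions", {
  set.seed(11)
  vals <- replicate(100, {
    x <- stats::setNames(sample(1:5, 200, TRUE), paste0("n", 1:200))
    y <- stats::setNames(sample(1:5, 200, TRUE), paste0("n", 1:200))
    ami(x, y)
  })
  expect_lt(abs(mean(vals)), 0.02)
  # while NMI stays positively biased on the same draws
  expect_gt(mean(replicate(20, {
    x <- stats::setNames(sample(1:5, 200, TRUE), paste0("n", 1:200))
    y <- stats::setNames(sample(1:5, 200, TRUE), paste0("n", 1:200))
    nmi(x, y)
  })), 0.02)
})

test_that("partitions expand through a merge map", {
  p <- stats::setNames(c(1L, 2L, 2L), c("72_81", "5", "6"))
  out <- expand_partition(p, list(`72_81` = c("72", "81")))
  expect_equal(out$assignment[c("72", "81")],
               c(`72` = 1L, `81` = 1L))
  expect_equal(out$assignment[c("5", "6")], c(`5` = 2L, `6` = 2L))
  expect_length(out$assignment, 4)

  # empty merge map: partition unchanged
  q <- stats::setNames(c(1L, 2L), c("a", "b"))
  expect_equal(expand_partition(q, list())$assignment, q)

  expect_error(expand_partition(p, list()), "missing from merge_map")
})
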