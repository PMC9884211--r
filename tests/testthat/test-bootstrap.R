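# tiny hand-built ensemble for the summary operations
fake_ensemble <- function(networks, partitions, empirical_partition,
                          ids = NULL) {
  ids <- ids %||% colnames(networks[[1]])
  reps <- purrr::map2(networks, partitions, function(w, p) {
    list(network = w, partition = p,
         n_communities = length(unique(netpsy:::partition_labels(p))))
  })
  structure(
    list(replicates = reps,
         empirical = list(network = networks[[1]],
                          partition = empirical_partition,
                          n_communities = length(unique(
                            netpsy:::partition_labels(empirical_partition)))),
         B = length(reps), seed = 0L, node_ids = ids, n_redrawn = 0L,
         corr_method = "pearson"),
    class = "netpsy_boot")
}

`%||%` <- rlang::`%||%`

test_that("the no-resampling seam reproduces the empirical network exactly", {
  g <- easy_synth(seed = 7, n = 400, factors = 2, items = 4)
  ens <- bootstrap_ega(g$data, B = 1, seed = 2, corr_method = "pearson",
                       spinglass = list(restarts = 2), resample = FALSE)
  expect_equal(ens$replicates[[1]]$network, ens$empirical$network,
               tolerance = 1e-12)
})

test_that("ensembles are a pure function of (data, config, seed)", {
  g <- easy_synth(seed = 7, n = 300, factors = 2, items = 4)
  a <- bootstrap_ega(g$data, B = 3, seed = 5, corr_method = "pearson",
                     spinglass = list(restarts = 1))
  b <- bootstrap_ega(g$data, B = 3, seed = 5, corr_method = "pearson",
                     spinglass = list(restarts = 1))
  expect_identical(purrr::map(a$replicates, "network"),
                   purrr::map(b$replicates, "network"))
  expect_identical(purrr::map(a$replicates, ~ .x$partition$assignment),
                   purrr::map(b$replicates, ~ .x$partition$assignment))
})

test_that("the bootstrap recovers the planted community count", {
  g <- easy_synth(seed = 17)
  ens <- bootstrap_ega(g$data, B = 30, seed = 3, corr_method = "pearson",
                       spinglass = list(restarts = 2))
  nc <- ncomm_distribution(ens)
  expect_equal(nc$mode, 4)
  expect_equal(nc$median, 4)
  # normal-approximation CI covers the replicate median
  expect_lte(nc$ci95_low, nc$median)
  expect_gte(nc$ci95_high, nc$median)
})

test_that("median_network takes elementwise medians", {
  ids <- c("a", "b")
  mk <- function(v) matrix(c(0, v, v, 0), 2, dimnames = list(ids, ids))
  p <- stats::setNames(c(1L, 1L), ids)
  ens <- fake_ensemble(list(mk(0.1), mk(0.2), mk(0.6)), list(p, p, p), p)
  med <- median_network(ens)
  expect_equal(med$weights["a", "b"], 0.2)
  expect_equal(med$weights, t(med$weights))
  # identical replicates: median equals any one of them
  ens2 <- fake_ensemble(list(mk(0.3), mk(0.3)), list(p, p), p)
  expect_equal(median_network(ens2)$weights, mk(0.3))
})

test_that("label alignment maps onto the reference and only relabels", {
  ref <- stats::setNames(c(1L, 1L, 2L, 2L), letters[1:4])
  swapped <- stats::setNames(c(2L, 2L, 1L, 1L), letters[1:4])
  expect_equal(align_labels(swapped, ref), ref)

  # a replicate splitting one reference community: the larger half keeps it
  ref2 <- stats::setNames(c(1L, 1L, 1L, 2L, 2L), letters[1:5])
  split <- stats::setNames(c(1L, 1L, 3L, 2L, 2L), letters[1:5])
  al <- align_labels(split, ref2)
  expect_equal(al[c("a", "b")], c(a = 1L, b = 1L))
  expect_equal(al[c("d", "e")], c(d = 2L, e = 2L))
  expect_false(al[["c"]] %in% c(1L, 2L))  # surplus label stays fresh

  # alignment never changes which nodes share a label
  set.seed(12)
  for (i in 1:10) {
    x <- stats::setNames(sample(1:3, 12, TRUE), letters[1:12])
    y <- stats::setNames(sample(1:4, 12, TRUE), letters[1:12])
    al2 <- align_labels(x, y)
    expect_identical(outer(al2, al2, "=="), outer(x, x, "=="))
  }
})

test_that("item stability and structural consistency read off the ensemble", {
  ids <- letters[1:6]
  w <- matrix(0, 6, 6, dimnames = list(ids, ids))
  emp <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), ids)
  intact <- emp
  split <- stats::setNames(c(1L, 1L, 3L, 2L, 2L, 3L), ids)
  ens <- fake_ensemble(list(w, w, w, w),
                       list(intact, intact, split, split), emp)
  st <- item_stability(ens)
  expect_equal(st$stability[st$item == "a"], 1)
  expect_equal(st$stability[st$item == "c"], 0.5)
  freq <- attr(st, "frequencies")
  expect_equal(rowSums(freq), stats::setNames(rep(1, 6), ids))

  sc <- structural_consistency(ens)
  # both dimensions lose a member in half the replicates
  expect_equal(sc$consistency, c(0.5, 0.5))
  # consistency is bounded by the weakest member's stability
  for (k in sc$community) {
    members <- st$item[st$empirical_community == k]
    expect_lte(sc$consistency[sc$community == k],
               min(st$stability[st$item %in% members]))
  }

  # fully stable ensemble: everything 1
  ens1 <- fake_ensemble(list(w, w), list(intact, intact), emp)
  expect_true(all(item_stability(ens1)$stability == 1))
  expect_true(all(structural_consistency(ens1)$consistency == 1))
})

test_that("stability is perfect when the pipeline is made deterministic", {
  g <- easy_synth(seed = 23, n = 600, factors = 2, items = 4)
  ens <- bootstrap_ega(g$data, B = 5, seed = 4, corr_method = "pearson",
                       spinglass = list(restarts = 3), resample = FALSE)
  expect_true(all(item_stability(ens)$stability == 1))
})

test_that("ncomm_distribution summarizes counts", {
  ids <- c("a", "b", "c")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  mk <- function(k) {
    labs <- rep_len(seq_len(k), 3)
    stats::setNames(as.integer(labs), ids)
  }
  ens <- fake_ensemble(list(w, w, w, w, w),
                       purrr::map(c(1, 2, 2, 2, 3), mk), mk(2))
  nc <- ncomm_distribution(ens)
  expect_equal(nc$mode, 2)
  expect_equal(nc$median, 2)
  expect_equal(nc$mean, 2)
  ens7 <- fake_ensemble(list(w, w), list(mk(3), mk(3)), mk(3))
  nc7 <- ncomm_distribution(ens7)
  expect_equal(nc7$sd, 0)
  expect_equal(c(nc7$ci95_low, nc7$ci95_high), c(3, 3))
})

test_that("case-drop stability behaves at the boundaries", {
  g <- easy_synth(seed = 19, n = 500, factors = 2, items = 4)
  cs0 <- case_drop_stability(g$data, metric = "strength",
                             drop_fractions = 0, B = 2, seed = 1,
                             corr_method = "pearson")
  expect_equal(cs0$detail$mean_cor, 1)
  expect_equal(cs0$detail$prop_above, 1)

  cs <- case_drop_stability(g$data, metric = "strength",
                            drop_fractions = c(0.1, 0.3), B = 5, seed = 1,
                            corr_method = "pearson")
  strict <- case_drop_stability(g$data, metric = "strength",
                                drop_fractions = c(0.1, 0.3), B = 5,
                                seed = 1, r_threshold = 0.95,
                                corr_method = "pearson")
  expect_lte(strict$cs_coefficient, cs$cs_coefficient)
  expect_error(case_drop_stability(g$data, drop_fractions = 1), "drop")
})
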