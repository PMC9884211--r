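#' Bootstrap exploratory graph analysis
#'
#' Replicates the estimate-then-partition pipeline over nonparametric
#' (row-resampling) bootstrap replicates: for each replicate, rows are drawn
#' with replacement, correlations estimated, the regularized network fit,
#' and spinglass communities detected. Degenerate resamples (an item
#' collapsing to one category, or a failed fit) are logged and redrawn.
#'
#' @param data Response tibble.
#' @param B Number of bootstrap replicates.
#' @param seed Base seed; replicate `b` uses child seed `seed + b`.
#' @param corr_method Correlation method for every fit.
#' @param gamma,n_lambda,lambda_min_ratio Network-estimation settings.
#' @param spinglass Named list of overrides for [spinglass_partition()]
#'   (e.g. `list(restarts = 2)`).
#' @param resample Set `FALSE` to disable resampling (every replicate sees
#'   the full data); a test seam for checking the pipeline's determinism.
#' @return A `netpsy_boot` ensemble: `replicates` (list of `network`
#'   weight matrix, `partition`, `n_communities`, `seed`), the `empirical`
#'   network and partition, `B`, `seed`, `n_redrawn`.
#' @export
bootstrap_ega <- function(data, B = 500, seed = 1,
                          corr_method = c("polychoric", "pearson"),
                          gamma = 0.5, n_lambda = 100,
                          lambda_min_ratio = 0.01,
                          spinglass = list(), resample = TRUE) {
  corr_method <- match.arg(corr_method)
  items <- item_cols(data)
  work <- data[items]
  n <- nrow(work)
  if (n < 50) warn("fewer than 50 respondents; bootstrap may be unstable")
  ordinal <- all(vapply(work, is.integer, logical(1)))
  use_method <- if (ordinal) corr_method else "pearson"

  fit_once <- function(d, sg_seed) {
    S <- item_correlations(d, method = use_method)
    net <- estimate_network(S, gamma = gamma, n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
    part <- do.call(spinglass_partition,
                    c(list(network = net, seed = sg_seed), spinglass))
    list(network = net$weights, partition = part,
         n_communities = length(unique(part$assignment)))
  }

  empirical <- fit_once(work, sg_seed = seed)
  replicates <- vector("list", B)
  n_redrawn <- 0L
  max_redraws <- max(1L, ceiling(0.1 * B))
  for (b in seq_len(B)) {
    rep_seed <- seed + b
    done <- FALSE
    while (!done) {
      set.seed(rep_seed)
      idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      res <- tryCatch(fit_once(work[idx, , drop = FALSE], sg_seed = rep_seed),
                      error = function(e) e)
      if (inherits(res, "error")) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraws) {
          abort(paste0("unstable resampling: more than 10% of replicates ",
                       "degenerate (last error: ",
                       conditionMessage(res), ")"))
        }
        rep_seed <- rep_seed + 7919L * n_redrawn   # redraw deterministically
      } else {
        res$seed <- rep_seed
        replicates[[b]] <- res
        done <- TRUE
      }
    }
  }
  structure(
    list(replicates = replicates, empirical = empirical, B = B, seed = seed,
         node_ids = items, n_redrawn = n_redrawn,
         corr_method = use_method),
    class = "netpsy_boot")
}

#' @export
print.netpsy_boot <- function(x, ...) {
  cat("<netpsy_boot> B = ", x$B, ", ", length(x$node_ids), " items, ",
      x$n_redrawn, " redraw(s)\n", sep = "")
  invisible(x)
}

#' Median network of a bootstrap ensemble
#'
#' Elementwise median of the replicate partial-correlation matrices; the
#' bias-robust summary network whose communities are reported.
#'
#' @param ensemble A `netpsy_boot`.
#' @return A `netpsy_network` with the median weights.
#' @export
median_network <- function(ensemble) {
  stopifnot(inherits(ensemble, "netpsy_boot"))
  mats <- purrr::map(ensemble$replicates, "network")
  arr <- simplify2array(mats)
  med <- apply(arr, c(1, 2), median)
  med <- (med + t(med)) / 2
  diag(med) <- 0
  dimnames(med) <- dimnames(mats[[1]])
  new_network(med, n = NA_integer_, correlation = ensemble$corr_method)
}

#' Align a replicate partition's labels onto a reference
#'
#' Solves the assignment problem on the contingency table (Hungarian
#' method): replicate labels are renamed to the reference labels that
#' maximize total node overlap. Surplus replicate labels (when the replicate
#' has more communities) keep fresh ids beyond the reference's. Only labels
#' change, never which nodes share one.
#'
#' @param partition Replicate partition.
#' @param reference Reference partition over the same nodes.
#' @return Named integer vector of aligned labels.
#' @export
align_labels <- function(partition, reference) {
  tab <- partition_contingency(partition, reference)
  rep_labs <- as.integer(rownames(tab))
  ref_labs <- as.integer(colnames(tab))
  k1 <- nrow(tab); k2 <- ncol(tab)
  k <- max(k1, k2)
  cost <- matrix(0, k, k)
  cost[seq_len(k1), seq_len(k2)] <- tab
  sol <- clue::solve_LSAP(cost, maximum = TRUE)
  mapping <- integer(k1)
  fresh <- max(ref_labs) # surplus labels continue after the reference's
  for (i in seq_len(k1)) {
    j <- sol[i]
    if (j <= k2) {
      mapping[i] <- ref_labs[j]
    } else {
      fresh <- fresh + 1L
      mapping[i] <- fresh
    }
  }
  lab <- partition_labels(partition)
  setNames(mapping[match(lab, rep_labs)], names(lab))
}

#' Item stability over a bootstrap ensemble
#'
#' Per item, the proportion of replicates in which the item's aligned
#' community equals its empirical one. The full item-by-dimension
#' replication-frequency table is attached as attribute `"frequencies"`.
#'
#' @param ensemble A `netpsy_boot`.
#' @return Tibble with `item`, `empirical_community`, `stability`;
#'   attribute `"frequencies"` holds the item x community proportion matrix.
#' @export
item_stability <- function(ensemble) {
  stopifnot(inherits(ensemble, "netpsy_boot"))
  ref <- ensemble$empirical$partition
  ref_lab <- partition_labels(ref)
  items <- names(ref_lab)
  aligned <- purrr::map(ensemble$replicates,
                        function(r) align_labels(r$partition, ref)[items])
  amat <- do.call(rbind, aligned)           # B x p
  labs_seen <- sort(unique(as.integer(amat)))
  freq <- vapply(labs_seen, function(l) colMeans(amat == l),
                 numeric(length(items)))
  dimnames(freq) <- list(items, as.character(labs_seen))
  stab <- freq[cbind(items, as.character(ref_lab[items]))]
  out <- tibble::tibble(item = items,
                        empirical_community = as.integer(ref_lab[items]),
                        stability = as.numeric(stab))
  attr(out, "frequencies") <- freq
  out
}

#' Structural consistency of the empirical dimensions
#'
#' Per empirical community, the proportion of replicates in which that exact
#' item set recurs as one community (no member missing, none added). With
#' `min_share < 1` the criterion relaxes to: some replicate community
#' contains at least that share of the dimension's items and nothing else.
#'
#' @param ensemble A `netpsy_boot`.
#' @param min_share Required share of the dimension recovered (default 1 =
#'   exact-set recovery).
#' @return Tibble with `community`, `n_items`, `consistency`.
#' @export
structural_consistency <- function(ensemble, min_share = 1) {
  stopifnot(inherits(ensemble, "netpsy_boot"))
  ref_lab <- partition_labels(ensemble$empirical$partition)
  dims <- split(names(ref_lab), ref_lab)
  hits <- setNames(numeric(length(dims)), names(dims))
  for (r in ensemble$replicates) {
    rl <- partition_labels(r$partition)
    groups <- split(names(rl), rl)
    for (d in names(dims)) {
      want <- dims[[d]]
      ok <- any(vapply(groups, function(g) {
        length(setdiff(g, want)) == 0 &&
          length(intersect(g, want)) >= min_share * length(want)
      }, logical(1)))
      if (ok) hits[d] <- hits[d] + 1
    }
  }
  tibble::tibble(community = as.integer(names(dims)),
                 n_items = lengths(dims),
                 consistency = as.numeric(hits) / length(ensemble$replicates))
}

#' Distribution of the number of detected communities
#'
#' Mode, median, mean, sd over the replicate community counts, and a 95%
#' normal-approximation interval `mean +/- 1.96 sd`.
#'
#' @param ensemble A `netpsy_boot`.
#' @return One-row tibble: `mode`, `median`, `mean`, `sd`, `ci95_low`,
#'   `ci95_high`.
#' @export
ncomm_distribution <- function(ensemble) {
  stopifnot(inherits(ensemble, "netpsy_boot"))
  if (ensemble$B < 2) abort("need at least 2 replicates")
  counts <- purrr::map_int(ensemble$replicates, "n_communities")
  tabc <- table(counts)
  tibble::tibble(
    mode = as.integer(names(tabc)[which.max(tabc)]),
    median = median(counts),
    mean = mean(counts),
    sd = sd(counts),
    ci95_low = mean(counts) - 1.96 * sd(counts),
    ci95_high = mean(counts) + 1.96 * sd(counts)
  )
}

#' Case-drop stability of a centrality metric
#'
#' For each drop fraction, draws `B` subsamples without replacement,
#' recomputes the network and metric, and correlates (Spearman) with the
#' full-sample metric. The correlation-stability (CS) coefficient is the
#' largest drop fraction at which at least 95% of correlations stay at or
#' above `r_threshold`.
#'
#' @param data Response tibble.
#' @param metric `"strength"`, `"ei1"`, or `"ei2"`.
#' @param drop_fractions Fractions of cases to drop.
#' @param B Subsamples per fraction.
#' @param seed Base seed.
#' @param r_threshold Correlation floor (default 0.7).
#' @param corr_method,gamma,n_lambda,lambda_min_ratio Pipeline settings.
#' @return List with `cs_coefficient` and `detail` (tibble: drop fraction,
#'   proportion of correlations >= threshold, mean correlation).
#' @export
case_drop_stability <- function(data, metric = c("strength", "ei1", "ei2"),
                                drop_fractions = seq(0.1, 0.7, by = 0.1),
                                B = 50, seed = 1, r_threshold = 0.7,
                                corr_method = c("polychoric", "pearson"),
                                gamma = 0.5, n_lambda = 100,
                                lambda_min_ratio = 0.01) {
  metric <- match.arg(metric)
  corr_method <- match.arg(corr_method)
  if (any(drop_fractions >= 1) || any(drop_fractions < 0)) {
    abort("drop fractions must be in [0, 1)")
  }
  items <- item_cols(data)
  work <- data[items]
  n <- nrow(work)
  metric_of <- function(d) {
    net <- network_from_data(d, method = corr_method, gamma = gamma,
                             n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio)
    switch(metric,
           strength = node_strength(net)$strength,
           ei1 = expected_influence(net, steps = 1)$ei,
           ei2 = expected_influence(net, steps = 2)$ei)
  }
  full <- metric_of(work)
  detail <- purrr::map_dfr(sort(drop_fractions), function(f) {
    keep <- max(3, round(n * (1 - f)))
    cors <- vapply(seq_len(B), function(b) {
      set.seed(seed + round(f * 1000) * 1000 + b)
      idx <- sample.int(n, keep)
      sub <- tryCatch(metric_of(work[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sub)) return(NA_real_)
      suppressWarnings(cor(full, sub, method = "spearman"))
    }, numeric(1))
    cors <- cors[!is.na(cors)]
    tibble::tibble(drop = f,
                   prop_above = mean(cors >= r_threshold),
                   mean_cor = mean(cors))
  })
  ok <- detail$drop[detail$prop_above >= 0.95]
  cs <- if (length(ok) == 0) 0 else max(ok)
  list(cs_coefficient = cs, detail = detail)
}
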