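#' Weighted topological overlap of a network
#'
#' \eqn{\omega_{ij} = (\sum_u |w_{iu}||w_{ju}| + |w_{ij}|) /
#' (\min(k_i, k_j) + 1 - |w_{ij}|)} with \eqn{k_i = \sum_u |w_{iu}|}: the
#' direct connection plus shared-neighbor connectivity, normalized so that
#' fully overlapping neighborhoods give 1. Diagonal set to 0 by convention.
#'
#' @param network A `netpsy_network` or symmetric weight matrix.
#' @return Symmetric overlap matrix with zero diagonal.
#' @export
wto <- function(network) {
  w <- abs(network_weights(network))
  stop_if_asymmetric(w, "network weight matrix")
  diag(w) <- 0
  num <- w %*% w + w
  k <- rowSums(w)
  kmin <- outer(k, k, pmin)
  den <- kmin + 1 - w
  omega <- num / den
  omega[den == 0] <- 0
  diag(omega) <- 0
  (omega + t(omega)) / 2
}

#' Upper-tail p-values for topological-overlap pairs
#'
#' Fits a null distribution to the nonzero overlap values and scores each
#' pair by its upper-tail probability; redundant pairs are those far in the
#' right tail.
#'
#' @param omega Overlap matrix from [wto()].
#' @param family `"gamma"` (method of moments, default), `"lognormal"`, or
#'   `"empirical"` (one minus the empirical CDF).
#' @return Tibble with `item_i`, `item_j`, `omega`, `p`, for nonzero pairs.
#' @export
redundancy_pvalues <- function(omega, family = c("gamma", "lognormal",
                                                 "empirical")) {
  family <- match.arg(family)
  stop_if_asymmetric(omega, "overlap matrix")
  pairs <- tidy_network_edges(omega)
  names(pairs) <- c("item_i", "item_j", "omega")
  pairs <- dplyr::filter(pairs, .data$omega > 0)
  if (nrow(pairs) < 10) {
    abort("too few nonzero overlap pairs to fit a null distribution (need >= 10)")
  }
  x <- pairs$omega
  if (family != "empirical" && var(x) == 0) {
    abort("degenerate overlap distribution: zero variance")
  }
  p <- switch(family,
    gamma = {
      shape <- mean(x)^2 / var(x)
      scale <- var(x) / mean(x)
      pgamma(x, shape = shape, scale = scale, lower.tail = FALSE)
    },
    lognormal = {
      lx <- log(x)
      pnorm(lx, mean = mean(lx), sd = sd(lx), lower.tail = FALSE)
    },
    empirical = {
      (rank(-x) - 0.5) / length(x)
    }
  )
  dplyr::arrange(dplyr::mutate(pairs, p = p), p)
}

#' Adaptive significance level for many overlap tests
#'
#' Scales a base alpha down with the number of tests:
#' \eqn{\alpha_{adapt} = \alpha \sqrt{n_{ref}(\log n_{ref} + q)} /
#' \sqrt{n(\log n + q)}}, where `q` is the upper `base_alpha` quantile of
#' \eqn{\chi^2_1}. Equal to `base_alpha` at `n_tests = n_ref` and decreasing
#' in `n_tests`.
#'
#' @param n_tests Number of tests performed (`>= 1`).
#' @param base_alpha Nominal level.
#' @param n_ref Reference test count at which no correction applies.
#' @return The corrected alpha.
#' @export
adaptive_alpha <- function(n_tests, base_alpha = 0.05, n_ref = 10) {
  if (n_tests < 1) abort("n_tests must be >= 1")
  q <- qchisq(base_alpha, df = 1, lower.tail = FALSE)
  base_alpha * sqrt(n_ref * (log(n_ref) + q)) /
    sqrt(n_tests * (log(n_tests) + q))
}

#' Group significant overlap pairs into chains and merge sets
#'
#' Chains are the connected components of the graph of significant pairs.
#' Within each chain the target is the item with maximal summed overlap; the
#' merge set is the target, its direct neighbors in the chain, and any item
#' sharing a clique of the chain with the target. Remaining chain members
#' are deferred to the next round.
#'
#' @param significant_pairs Tibble with `item_i`, `item_j` (rows = pairs).
#' @param omega Overlap matrix (for target selection).
#' @return List with `chains` (list of character vectors) and `merge_sets`
#'   (list of character vectors, each of size >= 2).
#' @export
build_merge_sets <- function(significant_pairs, omega) {
  if (is.null(significant_pairs) || nrow(significant_pairs) == 0) {
    return(list(chains = list(), merge_sets = list()))
  }
  g <- igraph::graph_from_data_frame(
    significant_pairs[c("item_i", "item_j")], directed = FALSE)
  comp <- igraph::components(g)
  chains <- split(names(comp$membership), comp$membership)
  merge_sets <- purrr::map(chains, function(members) {
    if (length(members) == 2) return(sort(members))
    sub <- igraph::induced_subgraph(g, members)
    osum <- rowSums(omega[members, members, drop = FALSE])
    target <- members[which.max(osum)]
    nbrs <- igraph::neighbors(sub, target)$name
    cliques <- igraph::max_cliques(sub, min = 3)
    in_clique <- unique(unlist(purrr::map(cliques, function(cl) {
      nm <- cl$name
      if (target %in% nm) nm else character(0)
    })))
    sort(unique(c(target, nbrs, in_clique)))
  })
  list(chains = purrr::map(chains, sort), merge_sets = unname(merge_sets))
}

#' Merge redundant items into composite variables
#'
#' Each merge set is replaced by one composite column named by its
#' underscore-joined source ids (e.g. `"72_81"`). With `method = "latent"` a
#' one-factor model is fit to the set (maximum likelihood for sets of three
#' or more items; the equal-loading closed form for pairs, whose one-factor
#' model is otherwise under-identified) and the regression-method factor
#' score replaces the sources; a Heywood case falls back to the mean score
#' with a warning. With `method = "sum"` the composite is the mean of the
#' source responses.
#'
#' @param data Response tibble.
#' @param merge_sets List of character vectors of item ids (disjoint).
#' @param method `"latent"` or `"sum"`.
#' @return Tibble with source columns replaced by composites. Composite
#'   columns are numeric scores, no longer ordinal.
#' @export
merge_items <- function(data, merge_sets, method = c("latent", "sum")) {
  method <- match.arg(method)
  if (length(merge_sets) == 0) return(data)
  all_src <- unlist(merge_sets)
  if (anyDuplicated(all_src) > 0) abort("merge sets must be disjoint")
  missing <- setdiff(all_src, names(data))
  if (length(missing) > 0) abort(paste0("unknown item: ", missing[1]))
  out <- data
  for (set in merge_sets) {
    comp_id <- paste(set, collapse = "_")
    x <- as.matrix(data[set])
    score <- if (method == "sum") rowMeans(x) else latent_score(x, comp_id)
    # composite takes the slot of its first source; other sources drop out
    before <- setdiff(names(out)[seq_len(match(set[1], names(out)) - 1)], set)
    after <- setdiff(names(out), c(before, set))
    out[[comp_id]] <- score
    out <- out[c(before, comp_id, setdiff(after, comp_id))]
  }
  out
}

# one-factor regression factor score; falls back to the mean on Heywood cases
latent_score <- function(x, comp_id) {
  z <- scale(x)
  R <- cor(x)
  k <- ncol(x)
  if (k == 2) {
    r <- R[1, 2]
    if (r <= 0) {
      warn(paste0("non-positive correlation in pair ", comp_id,
                  "; using mean score"))
      return(rowMeans(x))
    }
    lam <- rep(sqrt(r), 2)
  } else {
    fit <- tryCatch(factanal(covmat = R, factors = 1, n.obs = nrow(x)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warn(paste0("one-factor fit failed for ", comp_id, "; using mean score"))
      return(rowMeans(x))
    }
    lam <- as.numeric(fit$loadings)
    if (any(1 - lam^2 <= 1e-6)) {
      warn(paste0("Heywood case in ", comp_id, "; using mean score"))
      return(rowMeans(x))
    }
  }
  if (rcond(R) < 1e-10) {
    # collinear set (e.g. identical items): the factor is their common score
    return(as.numeric(rowMeans(z)))
  }
  wts <- solve(R, lam)           # regression (Thomson) scores
  as.numeric(z %*% wts)
}

#' Unique Variable Analysis: detect and merge redundant items
#'
#' Iterates correlate -> estimate network -> weighted topological overlap ->
#' null-fit p-values -> adaptive alpha -> chain/clique merge, until no pair
#' is significant or `max_rounds` is reached. Composite columns created in
#' one round take part in later rounds, so chains of redundancy collapse
#' progressively.
#'
#' @param data Response tibble (items only are used).
#' @param corr_method Correlation passed to [item_correlations()]. Composites
#'   created by merging are continuous, so later rounds use Pearson
#'   correlations automatically once any merge happened.
#' @param merge_method Passed to [merge_items()].
#' @param null_family Passed to [redundancy_pvalues()].
#' @param base_alpha,n_ref Passed to [adaptive_alpha()].
#' @param gamma,n_lambda,lambda_min_ratio Passed to [estimate_network()].
#' @param max_rounds Safety cap on merge rounds.
#' @return List with `data` (reduced tibble) and `report` (a
#'   `netpsy_uva_report`: per-round overlap/p-value tables, corrected
#'   alphas, chains, and `merge_map` = composite id -> source items).
#' @export
run_uva <- function(data, corr_method = c("polychoric", "pearson"),
                    merge_method = c("latent", "sum"),
                    null_family = "gamma",
                    base_alpha = 0.05, n_ref = 10,
                    gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                    max_rounds = 10) {
  corr_method <- match.arg(corr_method)
  merge_method <- match.arg(merge_method)
  diagnosis <- if ("diagnosis" %in% names(data)) data$diagnosis else NULL
  work <- data[item_cols(data)]
  rounds <- list()
  merge_map <- list()
  merged_any <- FALSE
  for (round in seq_len(max_rounds)) {
    use_method <- if (merged_any || any(!vapply(work, is.integer, logical(1))))
      "pearson" else corr_method
    S <- item_correlations(work, method = use_method)
    net <- estimate_network(S, gamma = gamma, n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
    omega <- wto(net)
    pv <- tryCatch(redundancy_pvalues(omega, family = null_family),
                   error = function(e) NULL)
    if (is.null(pv)) break
    alpha <- adaptive_alpha(nrow(pv), base_alpha = base_alpha, n_ref = n_ref)
    sig <- dplyr::filter(pv, .data$p < alpha)
    ms <- build_merge_sets(sig, omega)
    rounds[[round]] <- list(pvalues = pv, alpha = alpha,
                            chains = ms$chains, merge_sets = ms$merge_sets,
                            network = net, omega = omega)
    if (length(ms$merge_sets) == 0) break
    work <- merge_items(work, ms$merge_sets, method = merge_method)
    merged_any <- TRUE
    for (set in ms$merge_sets) {
      comp_id <- paste(set, collapse = "_")
      # expand any already-composite sources back to original items
      src <- unlist(purrr::map(set, function(s) merge_map[[s]] %||% s))
      merge_map[[comp_id]] <- unname(src)
      merge_map[setdiff(set, comp_id)] <- NULL
    }
  }
  if (!is.null(diagnosis)) work$diagnosis <- diagnosis
  report <- structure(
    list(rounds = rounds, merge_map = merge_map,
         n_rounds = length(rounds),
         n_items_in = length(item_cols(data)),
         n_items_out = length(item_cols(work))),
    class = "netpsy_uva_report")
  list(data = work, report = report)
}

#' @export
print.netpsy_uva_report <- function(x, ...) {
  cat("<netpsy_uva_report> ", x$n_items_in, " -> ", x$n_items_out,
      " items in ", x$n_rounds, " round(s); ",
      length(x$merge_map), " composite(s)\n", sep = "")
  invisible(x)
}

#' Merged-items table of a redundancy report
#'
#' One row per composite: the composite id and its comma-separated source
#' items, mirroring how merged nodes are tabulated in validation reports.
#'
#' @param report A `netpsy_uva_report`.
#' @return Tibble with `composite`, `sources`, `n_sources`.
#' @export
uva_merge_table <- function(report) {
  stopifnot(inherits(report, "netpsy_uva_report"))
  if (length(report$merge_map) == 0) {
    return(tibble::tibble(composite = character(0), sources = character(0),
                          n_sources = integer(0)))
  }
  tibble::tibble(
    composite = names(report$merge_map),
    sources = purrr::map_chr(report$merge_map, paste, collapse = ", "),
    n_sources = purrr::map_int(report$merge_map, length)
  )
}
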