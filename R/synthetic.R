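#' Specify a synthetic ordinal questionnaire
#'
#' Defines a multi-factor ordinal data-generating process: latent rows are
#' multivariate normal with covariance \eqn{\Lambda \Phi \Lambda^T + \Theta}
#' (unit total variance per item), then each latent value is cut at
#' `thresholds` into the ordinal codes `0..length(thresholds)`. Factors play
#' the role of questionnaire subscales; the planted item-to-factor map is
#' returned alongside the data so recovery can be scored.
#'
#' @param n_respondents Number of rows to draw.
#' @param n_factors Number of latent factors (planted communities).
#' @param items_per_factor Items loading on each factor.
#' @param loading Main loading magnitude in `[0, 1)`.
#' @param cross_loading Loading of every item on the next factor (cyclic);
#'   0 disables cross-loadings.
#' @param factor_corr Common inter-factor correlation in `(-1, 1)`.
#' @param thresholds Strictly increasing latent cut-points; the default
#'   `c(-1.5, -0.5, 0.5, 1.5)` yields a unimodal five-category Likert
#'   distribution.
#' @param swaps Optional named integer vector: item id -> new factor. Used to
#'   emulate cohort-specific structure (an item migrating between subscales)
#'   by regenerating with a modified loading matrix.
#' @param seed Integer seed; the draw is a pure function of the spec.
#' @return An object of class `netpsy_synth_spec`.
#' @export
synth_spec <- function(n_respondents = 1000, n_factors = 4,
                       items_per_factor = 5, loading = 0.7,
                       cross_loading = 0, factor_corr = 0.2,
                       thresholds = c(-1.5, -0.5, 0.5, 1.5),
                       swaps = NULL, seed = 1) {
  if (any(diff(thresholds) <= 0)) abort("thresholds must be strictly increasing")
  if (loading < 0 || loading >= 1) abort("loading must be in [0, 1)")
  if (abs(factor_corr) >= 1) abort("factor_corr must be in (-1, 1)")
  structure(
    list(n_respondents = as.integer(n_respondents),
         n_factors = as.integer(n_factors),
         items_per_factor = as.integer(items_per_factor),
         loading = loading, cross_loading = cross_loading,
         factor_corr = factor_corr, thresholds = thresholds,
         swaps = swaps, seed = as.integer(seed)),
    class = "netpsy_synth_spec"
  )
}

# loading matrix and factor correlation implied by a spec
synth_structure <- function(spec) {
  p <- spec$n_factors * spec$items_per_factor
  fac <- rep(seq_len(spec$n_factors), each = spec$items_per_factor)
  ids <- as.character(seq_len(p))
  names(fac) <- ids
  if (!is.null(spec$swaps)) {
    bad <- setdiff(names(spec$swaps), ids)
    if (length(bad) > 0) abort(paste0("swap names unknown item: ", bad[1]))
    fac[names(spec$swaps)] <- as.integer(spec$swaps)
  }
  L <- matrix(0, p, spec$n_factors, dimnames = list(ids, NULL))
  L[cbind(seq_len(p), fac)] <- spec$loading
  if (spec$cross_loading != 0) {
    nxt <- fac %% spec$n_factors + 1
    L[cbind(seq_len(p), nxt)] <- spec$cross_loading
  }
  Phi <- matrix(spec$factor_corr, spec$n_factors, spec$n_factors)
  diag(Phi) <- 1
  list(L = L, Phi = Phi, factors = fac, ids = ids)
}

#' Generate ordinal data with planted factor communities
#'
#' @param spec A [synth_spec()].
#' @return A list with `data` (response tibble, items `"1"`, `"2"`, ...,
#'   with the latent matrix attached as attribute `"latent"` so clones can
#'   be injected later), `partition` (planted item-to-factor
#'   `netpsy_partition`), and `spec`.
#' @export
generate_factor_data <- function(spec) {
  stopifnot(inherits(spec, "netpsy_synth_spec"))
  st <- synth_structure(spec)
  common <- st$L %*% st$Phi %*% t(st$L)
  uniq <- 1 - diag(common)
  if (any(uniq <= 0)) {
    abort(paste0("implied covariance not positive definite: uniqueness ",
                 signif(min(uniq), 4), " for item ",
                 st$ids[which.min(uniq)]))
  }
  Sigma <- common
  diag(Sigma) <- 1
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort(paste0("implied covariance not positive definite: eigenvalue ",
                 signif(min(ev), 4)))
  }
  set.seed(spec$seed)
  n <- spec$n_respondents
  p <- length(st$ids)
  Z <- matrix(rnorm(n * p), n, p)
  latent <- Z %*% chol(Sigma)
  colnames(latent) <- st$ids
  values <- discretize_latent(latent, spec$thresholds)
  data <- tibble::as_tibble(as.data.frame(values))
  names(data) <- st$ids
  attr(data, "latent") <- latent
  attr(data, "thresholds") <- spec$thresholds
  partition <- new_partition(setNames(as.integer(st$factors), st$ids),
                             method = "planted", seed = spec$seed)
  list(data = data, partition = partition, spec = spec)
}

discretize_latent <- function(latent, thresholds) {
  v <- matrix(findInterval(latent, vec = thresholds), nrow(latent),
              ncol(latent))
  storage.mode(v) <- "integer"
  colnames(v) <- colnames(latent)
  v
}

#' Append near-duplicate (redundant) clone items
#'
#' For every requested source item, appends a clone whose latent value is the
#' source's latent value plus Gaussian noise, re-discretized through the same
#' thresholds. This plants the local dependence that redundancy analysis is
#' meant to detect.
#'
#' @param data A response tibble produced by [generate_factor_data()] (it
#'   must carry the `"latent"` attribute).
#' @param pairs Named numeric vector: source item id -> noise standard
#'   deviation on the latent scale. May be empty.
#' @param seed Integer seed for the clone noise.
#' @param suffix Clone id = `paste0(item, suffix)`.
#' @return The tibble with clone columns appended; planted pairs recorded in
#'   attribute `"redundant_pairs"` (tibble: source, clone, noise_sd).
#' @export
inject_redundancy <- function(data, pairs, seed = 1, suffix = "r") {
  if (length(pairs) == 0) return(data)
  latent <- attr(data, "latent")
  thresholds <- attr(data, "thresholds")
  if (is.null(latent)) abort("`data` carries no latent attribute; generate it with generate_factor_data()")
  src <- names(pairs)
  bad <- setdiff(src, colnames(latent))
  if (length(bad) > 0) abort(paste0("unknown item: ", bad[1]))
  set.seed(seed)
  clones <- vapply(seq_along(src), function(i) {
    latent[, src[i]] + rnorm(nrow(latent), sd = pairs[i])
  }, numeric(nrow(latent)))
  clone_ids <- paste0(src, suffix)
  colnames(clones) <- clone_ids
  vals <- discretize_latent(clones, thresholds)
  out <- dplyr::bind_cols(data, tibble::as_tibble(as.data.frame(vals)))
  attr(out, "latent") <- cbind(latent, clones)
  attr(out, "thresholds") <- thresholds
  attr(out, "redundant_pairs") <-
    tibble::tibble(source = src, clone = clone_ids, noise_sd = unname(pairs))
  out
}

#' Simulate a multi-cohort sample with perturbed structure
#'
#' Draws one cohort per element of `cohorts`; each cohort may override the
#' sample size and migrate items between factors (`swaps`), emulating
#' diagnosis-specific structure. Cohort rows are stacked with a `diagnosis`
#' column.
#'
#' @param spec Base [synth_spec()].
#' @param cohorts Named list; each element a list with optional
#'   `n_respondents` and `swaps` overrides.
#' @return A list with `data` (stacked tibble with `diagnosis`) and
#'   `partitions` (planted partition per cohort).
#' @export
generate_cohorts <- function(spec, cohorts) {
  stopifnot(inherits(spec, "netpsy_synth_spec"))
  out <- purrr::imap(cohorts, function(cfg, label) {
    sp <- spec
    sp$n_respondents <- as.integer(cfg$n_respondents %||% spec$n_respondents)
    sp$swaps <- cfg$swaps %||% spec$swaps
    sp$seed <- spec$seed + match(label, names(cohorts))
    g <- generate_factor_data(sp)
    g$data$diagnosis <- label
    g
  })
  data <- dplyr::bind_rows(purrr::map(out, "data"))
  list(data = data, partitions = purrr::map(out, "partition"))
}
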