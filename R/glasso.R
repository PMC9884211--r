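#' Graphical lasso fit at a single penalty
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' \eqn{\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i\neq j} |\theta_{ij}|}
#' by blockwise coordinate descent. Convergence is declared when the largest
#' elementwise change of the working covariance in a full sweep falls below
#' `tol`.
#'
#' @param S Correlation (or covariance) matrix; must be symmetric PSD with
#'   unit-scale diagonal.
#' @param lambda Penalty, `>= 0`.
#' @param w_init Optional warm-start covariance estimate (used along a path).
#' @param maxit Maximum sweeps.
#' @param tol Convergence tolerance on the parameter change.
#' @return List with `theta` (precision), `w` (covariance estimate),
#'   `iterations`, `converged`.
#' @export
glasso_fit <- function(S, lambda, w_init = NULL, maxit = 10000, tol = 1e-6) {
  stop_if_asymmetric(S, "S")
  if (lambda < 0) abort("lambda must be >= 0")
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) abort("S is not positive semidefinite")
  if (lambda == 0 && ev_min < 1e-10) {
    abort("S is singular; lambda = 0 requires positive definite S")
  }
  fit <- .glasso_cd(unclass(S), lambda, w_init, maxit, tol)
  if (!fit$converged) {
    abort(paste0("graphical lasso did not converge in ", maxit,
                 " sweeps; residual change ", signif(fit$delta, 3)))
  }
  dimnames(fit$theta) <- dimnames(S)
  dimnames(fit$w) <- dimnames(S)
  fit[c("theta", "w", "iterations", "converged")]
}

#' Extended BIC of a precision matrix
#'
#' \eqn{-n[\log\det\Theta - \mathrm{tr}(S\Theta)] + E\log n + 4 E \gamma \log p},
#' where `E` counts nonzero upper-triangle entries of `theta` (entries below
#' `zero_tol` in absolute value are structural zeros).
#'
#' @param theta Positive-definite precision matrix.
#' @param S The correlation matrix the model was fit to.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter; 0 recovers the ordinary BIC.
#' @param zero_tol Numerical-noise floor for edge counting.
#' @return The EBIC score (smaller is better).
#' @export
ebic_score <- function(theta, S, n, gamma = 0.5, zero_tol = 1e-10) {
  p <- ncol(theta)
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) abort("theta is not positive definite")
  loglik <- as.numeric(ld$modulus) - sum(S * theta)
  E <- sum(abs(theta[upper.tri(theta)]) > zero_tol)
  -n * loglik + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a log-spaced penalty grid from
#' \eqn{\lambda_{max}} (the largest absolute off-diagonal correlation, the
#' smallest penalty giving an empty graph) down to
#' `lambda_max * lambda_min_ratio`, selects the penalty minimizing the
#' extended BIC, and converts the selected precision matrix to partial
#' correlations \eqn{\rho_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}}.
#'
#' @param S A `netpsy_corr` or correlation matrix.
#' @param n Sample size (taken from `S` when it carries one).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Grid size (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   \eqn{\lambda_{max}} (default 0.01).
#' @param lambdas Optional explicit penalty grid overriding the above.
#' @return A `netpsy_network`: list with `weights` (partial-correlation
#'   matrix, zero diagonal), `theta`, `lambda`, `gamma`, `n`, `node_ids`,
#'   `path` (tibble of lambda, edge count, EBIC).
#' @export
estimate_network <- function(S, n = NULL, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, lambdas = NULL) {
  n <- n %||% attr(S, "n")
  if (is.null(n)) abort("sample size `n` is required")
  method <- attr(S, "method") %||% "unknown"
  Sm <- unclass(S)
  attributes(Sm)[setdiff(names(attributes(Sm)), c("dim", "dimnames"))] <- NULL
  p <- ncol(Sm)
  ids <- colnames(Sm) %||% as.character(seq_len(p))
  dimnames(Sm) <- list(ids, ids)
  if (is.null(lambdas)) {
    lambda_max <- max(abs(Sm[upper.tri(Sm)]))
    if (lambda_max == 0) lambda_max <- 1e-4
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = n_lambda))
  }
  lambdas <- sort(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  w_warm <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- glasso_fit(Sm, lambdas[i], w_init = w_warm)
    w_warm <- fits[[i]]$w
  }
  scores <- vapply(fits, function(f) ebic_score(f$theta, Sm, n, gamma),
                   numeric(1))
  edges <- vapply(fits, function(f)
    sum(abs(f$theta[upper.tri(f$theta)]) > 1e-10), numeric(1))
  best <- which.min(scores)
  theta <- fits[[best]]$theta
  new_network(weights = precision_to_pcor(theta), theta = theta,
              lambda = lambdas[best], gamma = gamma, n = n,
              correlation = method,
              path = tibble::tibble(lambda = lambdas, n_edges = edges,
                                    ebic = scores))
}

#' Convert a precision matrix to partial correlations
#'
#' @param theta Precision matrix.
#' @param zero_tol Entries below this absolute value become exact zeros.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
precision_to_pcor <- function(theta, zero_tol = 1e-10) {
  d <- sqrt(diag(theta))
  w <- -theta / tcrossprod(d)
  diag(w) <- 0
  w[abs(w) < zero_tol] <- 0
  w <- (w + t(w)) / 2
  w
}

new_network <- function(weights, theta = NULL, lambda = NA_real_,
                        gamma = NA_real_, n = NA_integer_,
                        correlation = "unknown", path = NULL) {
  ids <- colnames(weights) %||% as.character(seq_len(ncol(weights)))
  dimnames(weights) <- list(ids, ids)
  structure(
    list(weights = weights, theta = theta, lambda = lambda, gamma = gamma,
         n = n, node_ids = ids, correlation = correlation, path = path),
    class = "netpsy_network"
  )
}

#' Build a network object from a raw weight matrix
#'
#' @param w Symmetric weight matrix (zero diagonal enforced).
#' @param n Optional sample size.
#' @return A `netpsy_network`.
#' @export
as_network <- function(w, n = NA_integer_) {
  stop_if_asymmetric(w, "weight matrix")
  diag(w) <- 0
  new_network(w, n = n)
}

# weight matrix from either representation
network_weights <- function(network) {
  if (inherits(network, "netpsy_network")) return(network$weights)
  if (is.matrix(network)) {
    ids <- colnames(network) %||% as.character(seq_len(ncol(network)))
    dimnames(network) <- list(ids, ids)
    return(network)
  }
  abort("not a network: expected netpsy_network or matrix")
}

#' Estimate a network straight from response data
#'
#' Convenience wrapper: correlations then [estimate_network()].
#'
#' @inheritParams item_correlations
#' @inheritParams estimate_network
#' @export
network_from_data <- function(data, method = c("polychoric", "pearson"),
                              gamma = 0.5, n_lambda = 100,
                              lambda_min_ratio = 0.01) {
  S <- item_correlations(data, method = method)
  estimate_network(S, gamma = gamma, n_lambda = n_lambda,
                   lambda_min_ratio = lambda_min_ratio)
}

#' @export
print.netpsy_network <- function(x, ...) {
  p <- length(x$node_ids)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("<netpsy_network> ", p, " nodes, ", ne, " edges",
      if (!is.na(x$lambda)) paste0(", lambda = ", signif(x$lambda, 4)),
      if (!is.na(x$n)) paste0(", n = ", x$n), "\n", sep = "")
  invisible(x)
}
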