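#' Item correlation matrix for ordinal responses
#'
#' Computes the correlation matrix feeding network estimation. The default is
#' the two-step polychoric estimator (thresholds from the univariate margins,
#' then per-pair maximum likelihood on the contingency table under a
#' bivariate normal), the convention for 0--4 Likert items; `"pearson"` gives
#' ordinary product-moment correlations. The result is smoothed to the
#' nearest positive-semidefinite correlation matrix when needed.
#'
#' @param data Response tibble (item columns; `diagnosis` ignored).
#' @param method `"polychoric"` or `"pearson"`.
#' @return A `netpsy_corr`: the correlation matrix with attributes `method`
#'   and `n`.
#' @export
item_correlations <- function(data, method = c("polychoric", "pearson")) {
  method <- match.arg(method)
  m <- response_values(data)
  if (method == "pearson") pearson_corr_matrix(m) else polychoric_corr_matrix(m)
}

new_corr <- function(values, method, n) {
  structure(values, method = method, n = n, class = c("netpsy_corr", "matrix"))
}

pearson_corr_matrix <- function(m) {
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant item: ", colnames(m)[which(sds == 0)[1]]))
  }
  r <- cor(m)
  new_corr(r, "pearson", nrow(m))
}

polychoric_corr_matrix <- function(m) {
  ncat <- apply(m, 2, function(v) length(unique(v)))
  if (any(ncat < 2)) {
    abort(paste0("item with a single observed category: ",
                 colnames(m)[which(ncat < 2)[1]]))
  }
  r <- .polychoric_matrix(m)
  dimnames(r) <- list(colnames(m), colnames(m))
  r <- nearest_psd(r)
  new_corr(r, "polychoric", nrow(m))
}

#' Two-step polychoric correlation of one item pair
#'
#' @param x,y Integer ordinal vectors coded from 0.
#' @return The maximum-likelihood correlation of the underlying bivariate
#'   normal, thresholds fixed at the inverse-normal marginal cumulative
#'   proportions.
#' @export
polychoric_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  .polychoric_pair(as.integer(x), as.integer(y))
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Clips eigenvalues at a small floor and rescales to unit diagonal; an
#' already-PSD matrix passes through unchanged (up to roundoff).
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor.
#' @return Symmetric PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(m, eps = 1e-8) {
  stop_if_asymmetric(m, "correlation matrix")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- cov2cor(out)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}

#' @export
print.netpsy_corr <- function(x, ...) {
  cat("<netpsy_corr> ", ncol(x), "x", ncol(x), " ", attr(x, "method"),
      " correlations, n = ", attr(x, "n"), "\n", sep = "")
  invisible(x)
}
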