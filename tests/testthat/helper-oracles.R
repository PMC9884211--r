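# Independent proximal-gradient (ISTA) optimizer of the off-diagonal L1
# penalized Gaussian log-likelihood; the reference the coordinate-descent
# solver is checked against.
glasso_oracle <- function(S, lambda, iters = 20000, tol = 1e-10) {
  pp <- ncol(S)
  Th <- diag(pp)
  smooth <- function(Th) {
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    -as.numeric(determinant(Th)$modulus) + sum(S * Th)
  }
  pen <- function(Th) 2 * lambda * sum(abs(Th[upper.tri(Th)]))
  eta <- 1
  f_old <- smooth(Th) + pen(Th)
  for (it in seq_len(iters)) {
    G <- S - solve(Th)
    repeat {
      Z <- Th - eta * G
      Zo <- sign(Z) * pmax(abs(Z) - eta * lambda, 0)
      diag(Zo) <- diag(Z)
      Zo <- (Zo + t(Zo)) / 2
      fs <- smooth(Zo)
      if (is.finite(fs) &&
          fs <= smooth(Th) + sum(G * (Zo - Th)) +
                sum((Zo - Th)^2) / (2 * eta)) break
      eta <- eta / 2
      if (eta < 1e-12) break
    }
    f_new <- fs + pen(Zo)
    done <- abs(f_old - f_new) < tol && max(abs(Zo - Th)) < 1e-8
    Th <- Zo
    f_old <- f_new
    if (done) break
    eta <- min(eta * 1.5, 1)
  }
  Th
}

# random correlation matrix with comfortable positive-definiteness
random_corr <- function(p) {
  A <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(A) + diag(p) * 0.5)
}

# exhaustive minimum of the signed Potts Hamiltonian over all partitions
# (set partitions enumerated via restricted growth strings); n <= 10 only
exhaustive_min_energy <- function(w, gamma_pos = 1, gamma_neg = 1) {
  n <- ncol(w)
  stopifnot(n <= 10)
  ids <- colnames(w)
  best <- Inf
  labels <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) {
      en <- partition_energy(w, stats::setNames(labels, ids),
                             gamma_pos, gamma_neg)
      if (en < best) best <<- en
      return(invisible())
    }
    for (l in seq_len(maxlab + 1)) {
      labels[i] <<- l
      recurse(i + 1, max(maxlab, l))
    }
  }
  recurse(1, 0)
  best
}

# small standard synthetic dataset shared across tests
easy_synth <- function(seed = 7, n = 1000, factors = 4, items = 5,
                       loading = 0.7, corr = 0.2) {
  generate_factor_data(synth_spec(
    n_respondents = n, n_factors = factors, items_per_factor = items,
    loading = loading, factor_corr = corr, seed = seed))
}
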