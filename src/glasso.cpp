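#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Graphical lasso by blockwise coordinate descent (Friedman et al. scheme):
// maximize log det Theta - tr(S Theta) - lambda * sum_{i != j} |theta_ij|.
// W is the working estimate of Sigma; each column's off-diagonal block is
// updated by an L1-penalized regression solved by coordinate descent.
// Convergence: max absolute change of W entries in a full sweep < tol.
// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix S, double lambda, Nullable<NumericMatrix> W0,
               int maxit = 10000, double tol = 1e-6) {
  int p = S.nrow();
  NumericMatrix W(p, p), Theta(p, p);
  std::vector<std::vector<double>> B(p, std::vector<double>(p, 0.0));

  if (W0.isNotNull()) {
    NumericMatrix w0(W0);
    for (int i = 0; i < p; i++)
      for (int j = 0; j < p; j++) W(i, j) = w0(i, j);
    // keep diagonal consistent with the current S
    for (int i = 0; i < p; i++) W(i, i) = S(i, i);
  } else {
    for (int i = 0; i < p; i++)
      for (int j = 0; j < p; j++) W(i, j) = S(i, j);
    for (int i = 0; i < p; i++) W(i, i) = S(i, i);
  }

  if (p == 1) {
    Theta(0, 0) = 1.0 / W(0, 0);
    return List::create(_["w"] = W, _["theta"] = Theta,
                        _["iterations"] = 0, _["converged"] = true,
                        _["delta"] = 0.0);
  }

  double delta = R_PosInf;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; it++) {
    delta = 0.0;
    for (int j = 0; j < p; j++) {
      // lasso for column j: minimize .5 b' W11 b - s12' b + lambda |b|_1
      std::vector<double> &b = B[j];
      // inner coordinate descent
      for (int inner = 0; inner < 1000; inner++) {
        double dmax = 0.0;
        for (int k = 0; k < p; k++) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; l++) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * b[l];
          }
          double bnew = soft(grad, lambda) / W(k, k);
          double ch = std::fabs(bnew - b[k]);
          if (ch > dmax) dmax = ch;
          b[k] = bnew;
        }
        if (dmax < tol * 0.1) break;
      }
      // update W(, j) = W11 %*% b
      for (int k = 0; k < p; k++) {
        if (k == j) continue;
        double v = 0.0;
        for (int l = 0; l < p; l++) {
          if (l == j) continue;
          v += W(k, l) * b[l];
        }
        double ch = std::fabs(v - W(k, j));
        if (ch > delta) delta = ch;
        W(k, j) = v;
        W(j, k) = v;
      }
    }
    if (delta < tol) { converged = true; break; }
  }

  // recover Theta from W and the regression coefficients
  for (int j = 0; j < p; j++) {
    double q = W(j, j);
    for (int k = 0; k < p; k++) {
      if (k == j) continue;
      q -= W(k, j) * B[j][k];
    }
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; k++) {
      if (k == j) continue;
      Theta(k, j) = -B[j][k] * tjj;
    }
  }
  // symmetrize (roundoff)
  for (int i = 0; i < p - 1; i++)
    for (int j = i + 1; j < p; j++) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["w"] = W, _["theta"] = Theta, _["iterations"] = it,
                      _["converged"] = converged, _["delta"] = delta);
}
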