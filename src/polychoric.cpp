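#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard normal CDF (Cody/erfc-based, double precision)
static inline double phid(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

// Bivariate standard-normal CDF P(X <= dh, Y <= dk), correlation r.
// Gauss-Legendre quadrature on Drezner & Wesolowsky's single-integral
// representation, node counts switched on |r| (the scheme used by Genz's
// BVND, which underlies the common Fortran implementations).
static double bvn_cdf(double dh, double dk, double r) {
  if (!std::isfinite(dh) && !std::isfinite(dk)) {
    if (dh < 0 || dk < 0) return 0.0;
    return 1.0;
  }
  if (!std::isfinite(dh)) return dh > 0 ? phid(dk) : 0.0;
  if (!std::isfinite(dk)) return dk > 0 ? phid(dh) : 0.0;

  static const double x6[] = {0.1252334085114689, 0.3678314989981802,
                              0.5873179542866175, 0.7699026741943047,
                              0.9041172563704749, 0.9815606342467192};
  static const double w6[] = {0.2491470458134028, 0.2334925365383548,
                              0.2031674267230659, 0.1600783285433462,
                              0.1069393259953184, 0.04717533638651183};
  static const double x12[] = {0.06405689286260563, 0.1911188674736163,
                               0.3150426796961634, 0.4337935076260451,
                               0.5454214713888396, 0.6480936519369755,
                               0.7401241915785544, 0.8200019859739029,
                               0.8864155270044011, 0.9382745520027328,
                               0.9747285559713095, 0.9951872199970213};
  static const double w12[] = {0.1279381953467522, 0.1258374563468283,
                               0.1216704729278034, 0.1155056680537256,
                               0.1074442701159656, 0.09761865210411389,
                               0.08619016153195327, 0.07334648141108031,
                               0.05929858491543678, 0.04427743881741981,
                               0.02853138862893366, 0.01234122979998720};
  static const double x20[] = {0.03877241750605082, 0.1160840706752552,
                               0.1926975807013711, 0.2681521850072537,
                               0.3419940908257585, 0.4137792043716050,
                               0.4830758016861787, 0.5494671250951282,
                               0.6125538896679802, 0.6719566846141796,
                               0.7273182551899271, 0.7783056514265194,
                               0.8246122308333117, 0.8659595032122595,
                               0.9020988069688743, 0.9328128082786765,
                               0.9579168192137917, 0.9772599499837743,
                               0.9907262386994570, 0.9982377097105593};
  static const double w20[] = {0.07750594797842481, 0.07703981816424797,
                               0.07611036190062624, 0.07472316905796826,
                               0.07288658239580406, 0.07061164739128678,
                               0.06791204581523390, 0.06480401345660104,
                               0.06130624249292894, 0.05743976909939155,
                               0.05322784698393682, 0.04869580763507223,
                               0.04387090818567327, 0.03878216797447202,
                               0.03346019528254785, 0.02793700698002340,
                               0.02224584919416696, 0.01642105838190789,
                               0.01049828453115281, 0.004521277098533191};

  const double *xg; const double *wg; int ng;
  double ar = std::fabs(r);
  if (ar < 0.3)      { xg = x6;  wg = w6;  ng = 6; }
  else if (ar < 0.75){ xg = x12; wg = w12; ng = 12; }
  else               { xg = x20; wg = w20; ng = 20; }

  double h = -dh, k = -dk;  // work with upper orthant P(X > dh, Y > dk) frame
  double hk = h * k, bvn = 0.0;

  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < ng; i++) {
      for (int s = -1; s <= 1; s += 2) {
        double sn = std::sin(asr * (s * xg[i] + 1.0) / 2.0);
        bvn += wg[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (4.0 * M_PI) + phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr0 = -(bs / as + hk) / 2.0;
      if (asr0 > -100.0) {
        bvn = a * std::exp(asr0) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      }
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(2.0 * M_PI) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < ng; i++) {
        for (int s = -1; s <= 1; s += 2) {
          double xs = a * (s * xg[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr1 = -(bs / xs + hk) / 2.0;
          if (asr1 > -100.0) {
            bvn += a * wg[i] * std::exp(asr1) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / (2.0 * M_PI);
    }
    if (r > 0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  // bvn currently = P(X > h', Y > k') in transformed frame = P(X<=dh, Y<=dk)
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// [[Rcpp::export(name = ".bvn_cdf")]]
NumericVector bvn_cdf_vec(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvn_cdf(h[i], k[i], r[i]);
  return out;
}

// Rectangle probability P(a1 < X <= a2, b1 < Y <= b2)
static inline double rect_prob(double a1, double a2, double b1, double b2,
                               double r) {
  double p = bvn_cdf(a2, b2, r) - bvn_cdf(a1, b2, r) -
             bvn_cdf(a2, b1, r) + bvn_cdf(a1, b1, r);
  return p > 1e-300 ? p : 1e-300;
}

// Negative log-likelihood of the contingency table under a bivariate
// normal with fixed thresholds and correlation rho.
static double pc_negll(const IntegerMatrix &tab, const NumericVector &ta,
                       const NumericVector &tb, double rho) {
  int R = tab.nrow(), C = tab.ncol();
  double ll = 0.0;
  for (int i = 0; i < R; i++) {
    double a1 = (i == 0) ? R_NegInf : ta[i - 1];
    double a2 = (i == R - 1) ? R_PosInf : ta[i];
    for (int j = 0; j < C; j++) {
      if (tab(i, j) == 0) continue;
      double b1 = (j == 0) ? R_NegInf : tb[j - 1];
      double b2 = (j == C - 1) ? R_PosInf : tb[j];
      ll += tab(i, j) * std::log(rect_prob(a1, a2, b1, b2, rho));
    }
  }
  return -ll;
}

// Brent's local minimizer on [a, b] (no derivatives), tol on x.
static double brent_min(const IntegerMatrix &tab, const NumericVector &ta,
                        const NumericVector &tb, double a, double b,
                        double tol, int *status) {
  const double gold = 0.5 * (3.0 - std::sqrt(5.0));
  double x = a + gold * (b - a), w = x, v = x;
  double fx = pc_negll(tab, ta, tb, x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  *status = 1;
  for (int iter = 0; iter < 200; iter++) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) { *status = 0; return x; }
    double p = 0.0, q = 0.0, rr = 0.0;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      rr = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * rr;
      q = 2.0 * (q - rr);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e; e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        parab = true;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
      }
    }
    if (!parab) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = pc_negll(tab, ta, tb, u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// Two-step polychoric for a pair of ordinal vectors coded 0..K.
// Thresholds from the univariate margins, rho by 1-D ML.
// [[Rcpp::export(name = ".polychoric_pair")]]
double polychoric_pair(IntegerVector x, IntegerVector y) {
  int n = x.size();
  int kx = 0, ky = 0;
  for (int i = 0; i < n; i++) {
    if (x[i] > kx) kx = x[i];
    if (y[i] > ky) ky = y[i];
  }
  IntegerMatrix tab(kx + 1, ky + 1);
  for (int i = 0; i < n; i++) tab(x[i], y[i])++;

  // margins; add 0.5 to every cell of an empty margin row/col never occurs
  // here because categories are taken from observed codes; but guard anyway
  NumericVector rowm(kx + 1), colm(ky + 1);
  for (int i = 0; i <= kx; i++)
    for (int j = 0; j <= ky; j++) { rowm[i] += tab(i, j); colm[j] += tab(i, j); }

  int nra = 0, nca = 0;
  for (int i = 0; i <= kx; i++) if (rowm[i] > 0) nra++;
  for (int j = 0; j <= ky; j++) if (colm[j] > 0) nca++;
  if (nra < 2 || nca < 2)
    stop("polychoric correlation undefined: an item has a single observed category");

  NumericVector ta(kx), tb(ky);
  double cum = 0.0;
  for (int i = 0; i < kx; i++) {
    cum += rowm[i];
    double p = cum / n;
    ta[i] = R::qnorm(p, 0.0, 1.0, 1, 0);
  }
  cum = 0.0;
  for (int j = 0; j < ky; j++) {
    cum += colm[j];
    double p = cum / n;
    tb[j] = R::qnorm(p, 0.0, 1.0, 1, 0);
  }

  int status = 0;
  double rho = brent_min(tab, ta, tb, -0.999, 0.999, 1e-7, &status);
  if (status != 0)
    stop("polychoric likelihood search did not converge");
  return rho;
}

// Full polychoric matrix over the columns of an integer matrix.
// [[Rcpp::export(name = ".polychoric_matrix")]]
NumericMatrix polychoric_matrix(IntegerMatrix data) {
  int p = data.ncol();
  NumericMatrix out(p, p);
  for (int i = 0; i < p; i++) out(i, i) = 1.0;
  for (int i = 0; i < p - 1; i++) {
    IntegerVector xi = data(_, i);
    for (int j = i + 1; j < p; j++) {
      IntegerVector yj = data(_, j);
      double r = polychoric_pair(xi, yj);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
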