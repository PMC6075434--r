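#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net
//
//   min_b  (1/2n) * || y - X b ||^2 + lambda * ( alpha*|b|_1 + (1-alpha)/2*|b|_2^2 )
//
// X is expected centered column-wise and y centered; the intercept is
// handled by the caller. xvar[j] = (1/n) * x_j' x_j (1 when columns are
// standardized to unit 1/n-variance). Columns with xvar[j] == 0 stay at 0.
// Convergence: largest coefficient update satisfies xvar_j * (db)^2 < tol.
//
// [[Rcpp::export]]
NumericVector cd_elnet_cpp(const NumericMatrix& X, const NumericVector& y,
                           double lambda, double alpha,
                           NumericVector beta_init,
                           const NumericVector& xvar,
                           double tol, int max_iter) {
  const int n = X.nrow();
  const int p = X.ncol();
  NumericVector b = clone(beta_init);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (b[j] != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * b[j];
    }
  }
  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);
  std::vector<bool> active(p, true);

  auto sweep = [&](bool full_pass) -> double {
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!full_pass && !active[j]) continue;
      if (xvar[j] <= 0.0) { b[j] = 0.0; continue; }
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += X(i, j) * r[i];
      g = g / n + xvar[j] * b[j];
      double bj;
      if (g > l1)       bj = (g - l1) / (xvar[j] + l2);
      else if (g < -l1) bj = (g + l1) / (xvar[j] + l2);
      else              bj = 0.0;
      double db = bj - b[j];
      if (db != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * db;
        b[j] = bj;
        double d = xvar[j] * db * db;
        if (d > maxd) maxd = d;
      }
      active[j] = (bj != 0.0);
    }
    return maxd;
  };

  for (int it = 0; it < max_iter; ++it) {
    // full pass to refresh the active set, then iterate on it
    double d_full = sweep(true);
    if (d_full < tol) break;
    for (int inner = 0; inner < max_iter; ++inner) {
      if (sweep(false) < tol) break;
    }
  }
  return b;
}
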