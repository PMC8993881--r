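#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the Brownian-bridge utilization density on a regular grid.
//
// For every consecutive fix pair with 0 < dt <= max_lag, the bridge
// contribution is the midpoint-rule average over n_alpha values of
// alpha in (0,1) of an isotropic bivariate normal density with mean
// z_i + alpha (z_{i+1} - z_i) and variance
// dt * alpha (1 - alpha) * sigma2 + ((1-alpha)^2 + alpha^2) * delta^2,
// weighted by dt / T_total. Values are density per unit area at cell
// centers; the caller multiplies by cell area and renormalizes.
//
// Each (pair, alpha) kernel is evaluated only within 7 standard
// deviations of its mean (relative truncation < 1e-10).
//
// Grid layout matches grid_spec: row 0 (C++) is the northernmost row,
// column 0 the westernmost; cell center (r, j) is at
// (x_min + (j + 0.5) c, y_min + (n_rows - r - 0.5) c).
//
// [[Rcpp::export]]
NumericMatrix bridge_density_cpp(NumericVector x, NumericVector y,
                                 NumericVector t_sec, double sigma2,
                                 double delta, double max_lag, int n_alpha,
                                 double x_min, double y_min, double cell,
                                 int n_cols, int n_rows) {
  NumericMatrix out(n_rows, n_cols);
  const int n = x.size();
  if (n < 2) return out;

  double t_total = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dt = t_sec[i + 1] - t_sec[i];
    if (dt > 0.0 && dt <= max_lag) t_total += dt;
  }
  if (t_total <= 0.0) return out;

  std::vector<double> gx(n_cols), gy(n_rows);
  const double two_pi = 2.0 * M_PI;

  for (int i = 0; i + 1 < n; ++i) {
    double dt = t_sec[i + 1] - t_sec[i];
    if (dt <= 0.0 || dt > max_lag) continue;
    double w_seg = dt / t_total / n_alpha;
    for (int a = 0; a < n_alpha; ++a) {
      double al = (a + 0.5) / n_alpha;
      double mx = x[i] + al * (x[i + 1] - x[i]);
      double my = y[i] + al * (y[i + 1] - y[i]);
      double v = dt * al * (1.0 - al) * sigma2 +
                 ((1.0 - al) * (1.0 - al) + al * al) * delta * delta;
      if (v < 1e-12) v = 1e-12;
      double halfwin = 7.0 * std::sqrt(v);
      int j0 = (int)std::floor((mx - halfwin - x_min) / cell - 0.5);
      int j1 = (int)std::ceil((mx + halfwin - x_min) / cell - 0.5);
      int r0 = (int)std::floor(n_rows - 0.5 - (my + halfwin - y_min) / cell);
      int r1 = (int)std::ceil(n_rows - 0.5 - (my - halfwin - y_min) / cell);
      if (j0 < 0) j0 = 0;
      if (j1 > n_cols - 1) j1 = n_cols - 1;
      if (r0 < 0) r0 = 0;
      if (r1 > n_rows - 1) r1 = n_rows - 1;
      if (j0 > j1 || r0 > r1) continue;
      double coef = w_seg / (two_pi * v);
      double inv2v = 1.0 / (2.0 * v);
      for (int j = j0; j <= j1; ++j) {
        double d = x_min + (j + 0.5) * cell - mx;
        gx[j] = std::exp(-d * d * inv2v);
      }
      for (int r = r0; r <= r1; ++r) {
        double d = y_min + (n_rows - r - 0.5) * cell - my;
        gy[r] = std::exp(-d * d * inv2v);
      }
      for (int j = j0; j <= j1; ++j) {
        double cg = coef * gx[j];
        for (int r = r0; r <= r1; ++r) out(r, j) += cg * gy[r];
      }
    }
  }
  return out;
}
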