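#include <Rcpp.h>
using namespace Rcpp;

// Residuals of the ARMA recursion
//   e_t = y_t - c - sum_i phi_i y_{t-i} - sum_j theta_j e_{t-j},
// zero-initialised for t <= max(p, q) (conditional-sum-of-squares convention).
// [[Rcpp::export]]
NumericVector css_residuals_cpp(const NumericVector& y, double c,
                                const NumericVector& phi,
                                const NumericVector& theta) {
  const int n = y.size();
  const int p = phi.size();
  const int q = theta.size();
  const int m = std::max(p, q);
  NumericVector e(n);
  for (int t = m; t < n; ++t) {
    double v = y[t] - c;
    for (int i = 0; i < p; ++i) v -= phi[i] * y[t - 1 - i];
    for (int j = 0; j < q; ++j) v -= theta[j] * e[t - 1 - j];
    e[t] = v;
  }
  return e;
}

// Map partial autocorrelations (tanh of unconstrained reals) to AR
// coefficients by the Durbin-Levinson recursion.
static void pacf_to_coef_cpp(const double* u, int k, std::vector<double>& a) {
  a.assign(k, 0.0);
  std::vector<double> tmp(k);
  for (int j = 0; j < k; ++j) {
    double r = std::tanh(u[j]);
    for (int i = 0; i < j; ++i) tmp[i] = a[i] - r * a[j - 1 - i];
    for (int i = 0; i < j; ++i) a[i] = tmp[i];
    a[j] = r;
  }
}

// Concentrated CSS objective log(RSS / n_used) evaluated directly from the
// unconstrained parameter vector (constant?, AR partials, MA partials);
// called once per optimiser function evaluation.
// [[Rcpp::export]]
double css_objective_cpp(const NumericVector& par, const NumericVector& y,
                         int p, int q, bool est_const) {
  int i0 = est_const ? 1 : 0;
  double c = est_const ? par[0] : 0.0;
  const double* base = REAL(par);
  std::vector<double> phi, theta;
  pacf_to_coef_cpp(base + i0, p, phi);
  pacf_to_coef_cpp(base + i0 + p, q, theta);
  for (int j = 0; j < q; ++j) theta[j] = -theta[j];
  const int n = y.size();
  const int m = std::max(p, q);
  std::vector<double> e(q > 0 ? n : 0);
  double rss = 0.0;
  for (int t = m; t < n; ++t) {
    double v = y[t] - c;
    for (int i = 0; i < p; ++i) v -= phi[i] * y[t - 1 - i];
    for (int j = 0; j < q; ++j) v -= theta[j] * e[t - 1 - j];
    if (q > 0) e[t] = v;
    rss += v * v;
  }
  if (!std::isfinite(rss) || rss <= 0.0) return 1e10;
  return std::log(rss / (n - m));
}

// Sum of squared conditional residuals over t > max(p, q); avoids the
// allocation in css_residuals_cpp inside the optimiser's inner loop.
// [[Rcpp::export]]
double css_rss_cpp(const NumericVector& y, double c,
                   const NumericVector& phi,
                   const NumericVector& theta) {
  const int n = y.size();
  const int p = phi.size();
  const int q = theta.size();
  const int m = std::max(p, q);
  std::vector<double> e(q > 0 ? n : 0);
  double rss = 0.0;
  for (int t = m; t < n; ++t) {
    double v = y[t] - c;
    for (int i = 0; i < p; ++i) v -= phi[i] * y[t - 1 - i];
    for (int j = 0; j < q; ++j) v -= theta[j] * e[t - 1 - j];
    if (q > 0) e[t] = v;
    rss += v * v;
  }
  return rss;
}
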