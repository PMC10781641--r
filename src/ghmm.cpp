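#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// EM for a univariate Gaussian-emission hidden Markov model with scaled
// forward-backward recursions. Emission densities are floored at 1e-300 and
// state variances at var_floor to keep the recursion finite when a state
// collapses onto few points.
// [[Rcpp::export]]
List ghmm_em_cpp(NumericVector x, NumericVector init0, NumericMatrix trans0,
                 NumericVector means0, NumericVector vars0,
                 int max_iter, double tol, double var_floor) {
  const int n = x.size(), k = means0.size();
  std::vector<double> pi(init0.begin(), init0.end());
  NumericMatrix A = clone(trans0);
  std::vector<double> mu(means0.begin(), means0.end());
  std::vector<double> s2(vars0.begin(), vars0.end());
  NumericMatrix B(n, k), alpha(n, k), beta(n, k), gam(n, k);
  std::vector<double> c(n);
  double ll = R_NegInf, prev_ll = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission densities
    for (int j = 0; j < k; ++j) {
      double inv2 = 0.5 / s2[j];
      double norm = 1.0 / std::sqrt(2.0 * M_PI * s2[j]);
      for (int t = 0; t < n; ++t) {
        double d = x[t] - mu[j];
        double b = norm * std::exp(-d * d * inv2);
        B(t, j) = (b < 1e-300) ? 1e-300 : b;
      }
    }
    // forward (scaled)
    double ct = 0.0;
    for (int j = 0; j < k; ++j) { alpha(0, j) = pi[j] * B(0, j); ct += alpha(0, j); }
    if (ct <= 0) return List::create(_["ok"] = false);
    c[0] = ct;
    for (int j = 0; j < k; ++j) alpha(0, j) /= ct;
    for (int t = 1; t < n; ++t) {
      ct = 0.0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int i = 0; i < k; ++i) s += alpha(t - 1, i) * A(i, j);
        double a = s * B(t, j);
        alpha(t, j) = a; ct += a;
      }
      if (ct <= 0) return List::create(_["ok"] = false);
      c[t] = ct;
      for (int j = 0; j < k; ++j) alpha(t, j) /= ct;
    }
    ll = 0.0;
    for (int t = 0; t < n; ++t) ll += std::log(c[t]);
    // backward (scaled)
    for (int j = 0; j < k; ++j) beta(n - 1, j) = 1.0;
    for (int t = n - 2; t >= 0; --t)
      for (int i = 0; i < k; ++i) {
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += A(i, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, i) = s / c[t + 1];
      }
    // posteriors and expected transition counts
    std::vector<double> xi_num(k * k, 0.0);
    for (int t = 0; t < n; ++t) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) { gam(t, j) = alpha(t, j) * beta(t, j); s += gam(t, j); }
      for (int j = 0; j < k; ++j) gam(t, j) /= s;
    }
    for (int t = 0; t < n - 1; ++t)
      for (int i = 0; i < k; ++i) {
        double ai = alpha(t, i);
        if (ai <= 0) continue;
        for (int j = 0; j < k; ++j)
          xi_num[i * k + j] += ai * A(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
      }
    // M-step
    for (int j = 0; j < k; ++j) pi[j] = gam(0, j);
    for (int i = 0; i < k; ++i) {
      double denom = 0.0;
      for (int j = 0; j < k; ++j) denom += xi_num[i * k + j];
      if (denom > 0)
        for (int j = 0; j < k; ++j) A(i, j) = xi_num[i * k + j] / denom;
    }
    for (int j = 0; j < k; ++j) {
      double w = 0.0, wx = 0.0;
      for (int t = 0; t < n; ++t) { w += gam(t, j); wx += gam(t, j) * x[t]; }
      if (w > 0) {
        mu[j] = wx / w;
        double wv = 0.0;
        for (int t = 0; t < n; ++t) {
          double d = x[t] - mu[j];
          wv += gam(t, j) * d * d;
        }
        s2[j] = wv / w;
      }
      if (s2[j] < var_floor) s2[j] = var_floor;
    }
    if (iter > 0 && std::fabs(ll - prev_ll) < tol * (std::fabs(ll) + 1.0)) {
      converged = true;
      break;
    }
    prev_ll = ll;
  }
  return List::create(_["ok"] = true, _["loglik"] = ll,
                      _["init"] = NumericVector(pi.begin(), pi.end()),
                      _["trans"] = A,
                      _["means"] = NumericVector(mu.begin(), mu.end()),
                      _["vars"] = NumericVector(s2.begin(), s2.end()),
                      _["converged"] = converged, _["iterations"] = iter + 1);
}
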