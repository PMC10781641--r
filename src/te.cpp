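#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in Shannon transfer entropy in bits over integer symbol sequences
// (symbols 1..ax / 1..ay), histories of length 'order' for both source and
// target. Joint frequencies are accumulated in flat count arrays.
static double te_counts(const int *xs, const int *ys, int n, int ax, int ay,
                        int order) {
  long long ayk = 1, axl = 1;
  for (int j = 0; j < order; ++j) { ayk *= ay; axl *= ax; }
  long long size1 = (long long)ay * ayk * axl;
  if (size1 > 50000000LL)
    stop("state space too large for the plug-in estimator");
  std::vector<int> c1((size_t)size1, 0), c2((size_t)(ayk * axl), 0),
      c3((size_t)(ay * ayk), 0), c4((size_t)ayk, 0);
  int N = 0;
  for (int t = order; t < n; ++t) {
    long long yk = 0, xl = 0;
    for (int j = 1; j <= order; ++j) {
      yk = yk * ay + (ys[t - j] - 1);
      xl = xl * ax + (xs[t - j] - 1);
    }
    long long yp = ys[t] - 1;
    ++c1[(size_t)((yp * ayk + yk) * axl + xl)];
    ++c2[(size_t)(yk * axl + xl)];
    ++c3[(size_t)(yp * ayk + yk)];
    ++c4[(size_t)yk];
    ++N;
  }
  if (N == 0) stop("undefined transfer entropy: empty joint support");
  double te = 0.0;
  for (long long idx = 0; idx < size1; ++idx) {
    int n1 = c1[(size_t)idx];
    if (n1 == 0) continue;
    long long xl = idx % axl, rest = idx / axl;
    long long yk = rest % ayk, yp = rest / ayk;
    double n2 = c2[(size_t)(yk * axl + xl)];
    double n3 = c3[(size_t)(yp * ayk + yk)];
    double n4 = c4[(size_t)yk];
    te += (double)n1 / N * std::log2((double)n1 * n4 / (n2 * n3));
  }
  return te;
}

// [[Rcpp::export]]
double te_cpp(IntegerVector xs, IntegerVector ys, int ax, int ay, int order) {
  if (xs.size() != ys.size()) stop("sequences must have equal length");
  if (xs.size() <= order) stop("sequence shorter than the history length");
  return te_counts(xs.begin(), ys.begin(), xs.size(), ax, ay, order);
}

// Transfer entropy for block-bootstrap surrogate sources. 'starts' holds
// 1-based block start positions, one row per surrogate; consecutive blocks
// of length 'block_len' are concatenated and trimmed to the series length.
// [[Rcpp::export]]
NumericVector te_boot_cpp(IntegerVector xs, IntegerVector ys, int ax, int ay,
                          int order, IntegerMatrix starts, int block_len) {
  const int n = xs.size();
  if (ys.size() != n) stop("sequences must have equal length");
  NumericVector out(starts.nrow());
  std::vector<int> sur(n);
  for (int b = 0; b < starts.nrow(); ++b) {
    int pos = 0;
    for (int j = 0; j < starts.ncol() && pos < n; ++j) {
      int s = starts(b, j) - 1;
      for (int l = 0; l < block_len && pos < n; ++l) sur[pos++] = xs[s + l];
    }
    if (pos < n) stop("not enough blocks to cover the series");
    out[b] = te_counts(sur.data(), ys.begin(), n, ax, ay, order);
  }
  return out;
}
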