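#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy pairwise-swap descent that reorders a series so that its lag-1..max_lag
// autocorrelations approach those of the original ordering, starting from a
// given permutation. Used to build surrogates that keep the amplitude multiset
// exactly (the output is a permutation) while restoring the autocorrelation
// structure. Uses R's RNG: seed with set.seed() before calling.
//
// x:        series in its original order (defines the target autocorrelations)
// init:     1-based starting permutation of x
// max_lag:  number of autocorrelation lags to match
// max_sweeps: each sweep proposes length(x) random swaps
// tol:      stop when the summed squared autocorrelation discrepancy falls below
// Returns the 1-based permutation found.
// [[Rcpp::export]]
IntegerVector acf_swap_descent(NumericVector x, IntegerVector init, int max_lag,
                               int max_sweeps, double tol) {
  const int n = x.size();
  if (init.size() != n) stop("init must be a permutation of seq_along(x)");
  if (max_lag < 1 || max_lag >= n) stop("max_lag must be in [1, n-1]");
  const double mu = mean(x);
  std::vector<double> v(n);          // centered values in surrogate order
  std::vector<int> perm(n);
  double c0 = 0.0;
  for (int i = 0; i < n; ++i) {
    perm[i] = init[i] - 1;
    v[i] = x[perm[i]] - mu;
  }
  std::vector<double> vx(n);         // centered values in original order
  for (int i = 0; i < n; ++i) {
    vx[i] = x[i] - mu;
    c0 += vx[i] * vx[i];
  }
  if (c0 <= 0.0) return init;        // constant series: nothing to match

  // target and current autocovariance sums per lag
  std::vector<double> target(max_lag + 1, 0.0), cur(max_lag + 1, 0.0);
  for (int L = 1; L <= max_lag; ++L) {
    for (int i = 0; i + L < n; ++i) {
      target[L] += vx[i] * vx[i + L];
      cur[L] += v[i] * v[i + L];
    }
  }
  double obj = 0.0;
  for (int L = 1; L <= max_lag; ++L) {
    double r = (cur[L] - target[L]) / c0;
    obj += r * r;
  }

  std::vector<double> newcur(max_lag + 1);
  GetRNGstate();
  long total = (long)max_sweeps * n;
  for (long it = 0; it < total && obj > tol; ++it) {
    int a = (int)std::floor(unif_rand() * n);
    int b = (int)std::floor(unif_rand() * n);
    if (a >= n) a = n - 1;
    if (b >= n) b = n - 1;
    if (a == b) continue;
    if (a > b) std::swap(a, b);
    double newobj = 0.0;
    for (int L = 1; L <= max_lag; ++L) {
      // product terms v[i]*v[i+L] touched by swapping positions a and b
      int cand[4] = {a - L, a, b - L, b};
      double before = 0.0, after = 0.0;
      for (int m = 0; m < 4; ++m) {
        int i = cand[m];
        if (i < 0 || i + L >= n) continue;
        bool dup = false;               // count each term once
        for (int mm = 0; mm < m; ++mm)
          if (cand[mm] == i) { dup = true; break; }
        if (dup) continue;
        before += v[i] * v[i + L];
        double vi = (i == a) ? v[b] : (i == b ? v[a] : v[i]);
        int j = i + L;
        double vj = (j == a) ? v[b] : (j == b ? v[a] : v[j]);
        after += vi * vj;
      }
      newcur[L] = cur[L] - before + after;
      double r = (newcur[L] - target[L]) / c0;
      newobj += r * r;
    }
    if (newobj < obj) {
      std::swap(v[a], v[b]);
      std::swap(perm[a], perm[b]);
      for (int L = 1; L <= max_lag; ++L) cur[L] = newcur[L];
      obj = newobj;
    }
  }
  PutRNGstate();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = perm[i] + 1;
  return out;
}
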