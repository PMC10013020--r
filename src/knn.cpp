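#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// max-norm (Chebyshev) distance between row i of a and row j of b
static inline double chebyshev(const NumericMatrix& a, int i,
                               const NumericMatrix& b, int j) {
  double d = 0.0;
  const int nc = a.ncol();
  for (int c = 0; c < nc; ++c) {
    double v = std::fabs(a(i, c) - b(j, c));
    if (v > d) d = v;
  }
  return d;
}

// Distance from each query row to its k-th nearest neighbor among the rows of
// ref, under the maximum norm. If exclude_self is true, query and ref are the
// same matrix and row i of ref is skipped when querying row i.
// [[Rcpp::export]]
NumericVector knn_max_dist(NumericMatrix query, NumericMatrix ref, int k,
                           bool exclude_self) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != ref.ncol())
    stop("query and ref must have the same number of columns");
  const int avail = exclude_self ? nr - 1 : nr;
  if (k < 1 || k > avail)
    stop("k must be between 1 and the number of available reference rows");
  NumericVector out(nq);
  std::vector<double> d;
  d.reserve(nr);
  for (int i = 0; i < nq; ++i) {
    d.clear();
    for (int j = 0; j < nr; ++j) {
      if (exclude_self && j == i) continue;
      d.push_back(chebyshev(query, i, ref, j));
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    out[i] = d[k - 1];
  }
  return out;
}

// Indices (1-based) of the n_neighbors nearest rows of ref for each query row,
// max norm, ties broken by row order. Rows of the result are sorted by
// increasing distance. exclude_self as above.
// [[Rcpp::export]]
IntegerMatrix knn_neighbor_indices(NumericMatrix query, NumericMatrix ref,
                                   int n_neighbors, bool exclude_self) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != ref.ncol())
    stop("query and ref must have the same number of columns");
  const int avail = exclude_self ? nr - 1 : nr;
  if (n_neighbors < 1 || n_neighbors > avail)
    stop("n_neighbors must be between 1 and the number of available reference rows");
  IntegerMatrix out(nq, n_neighbors);
  std::vector<std::pair<double, int> > d;
  d.reserve(nr);
  for (int i = 0; i < nq; ++i) {
    d.clear();
    for (int j = 0; j < nr; ++j) {
      if (exclude_self && j == i) continue;
      d.push_back(std::make_pair(chebyshev(query, i, ref, j), j));
    }
    std::partial_sort(d.begin(), d.begin() + n_neighbors, d.end());
    for (int m = 0; m < n_neighbors; ++m) out(i, m) = d[m].second + 1;
  }
  return out;
}

// Number of ref rows strictly within per-query max-norm radius eps[i].
// exclude_self as above (query and ref are the same matrix).
// [[Rcpp::export]]
IntegerVector range_count_max(NumericMatrix query, NumericMatrix ref,
                              NumericVector eps, bool exclude_self) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != ref.ncol())
    stop("query and ref must have the same number of columns");
  if (eps.size() != nq) stop("eps must have one radius per query row");
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    int cnt = 0;
    for (int j = 0; j < nr; ++j) {
      if (exclude_self && j == i) continue;
      if (chebyshev(query, i, ref, j) < eps[i]) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
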