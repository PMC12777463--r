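#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest-neighbour search in 2D by exhaustive scan with partial
// selection. Self is excluded; distance ties broken by ascending cell index
// so results are deterministic across platforms.

struct Cand {
  double d2;
  int idx; // 0-based
};

static inline bool cand_less(const Cand &a, const Cand &b) {
  if (a.d2 != b.d2) return a.d2 < b.d2;
  return a.idx < b.idx;
}

// [[Rcpp::export]]
List knn_brute_cpp(NumericVector x, NumericVector y, IntegerVector query,
                   int k) {
  const int n = x.size();
  const int q = query.size();
  if (k < 1) stop("k must be at least 1");
  if (k >= n) stop("k must be smaller than the number of cells");

  IntegerMatrix idx(q, k);
  NumericMatrix dist(q, k);
  std::vector<Cand> cand(n - 1);

  for (int qi = 0; qi < q; ++qi) {
    const int self = query[qi] - 1; // 1-based from R
    const double qx = x[self], qy = y[self];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == self) continue;
      const double dx = x[j] - qx, dy = y[j] - qy;
      cand[m].d2 = dx * dx + dy * dy;
      cand[m].idx = j;
      ++m;
    }
    std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end(),
                     cand_less);
    std::sort(cand.begin(), cand.begin() + k, cand_less);
    for (int j = 0; j < k; ++j) {
      idx(qi, j) = cand[j].idx + 1;
      dist(qi, j) = std::sqrt(cand[j].d2);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Per-cell k-neighbour cell-type counts for every cell of the slide in one
// pass; used by the permutation null, where all cells are candidate
// resamples. type is a 1-based integer code per cell, n_types its maximum.
// [[Rcpp::export]]
IntegerMatrix knn_type_counts_cpp(NumericVector x, NumericVector y,
                                  IntegerVector type, int n_types, int k) {
  const int n = x.size();
  if (k < 1) stop("k must be at least 1");
  if (k >= n) stop("k must be smaller than the number of cells");

  IntegerMatrix counts(n, n_types);
  std::vector<Cand> cand(n - 1);

  for (int self = 0; self < n; ++self) {
    const double qx = x[self], qy = y[self];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == self) continue;
      const double dx = x[j] - qx, dy = y[j] - qy;
      cand[m].d2 = dx * dx + dy * dy;
      cand[m].idx = j;
      ++m;
    }
    std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end(),
                     cand_less);
    for (int j = 0; j < k; ++j) {
      // only the k smallest matter; order within them does not affect counts
      counts(self, type[cand[j].idx] - 1) += 1;
    }
    // nth_element left elements [0,k) as the k smallest but unsorted beyond
    // position k-1; re-scan not needed since counts ignore order.
  }
  return counts;
}
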