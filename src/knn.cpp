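#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// For each query row, the fraction of its k nearest target rows (euclidean)
// carrying label 1. self_index (0-based into target, -1 = none) marks the
// target row that is the query itself and is excluded.
// [[Rcpp::export]]
NumericVector knn_label_fraction_cpp(NumericMatrix query, NumericMatrix target,
                                     IntegerVector labels, int k,
                                     IntegerVector self_index) {
  int nq = query.nrow(), nt = target.nrow(), d = query.ncol();
  if (target.ncol() != d) stop("dimension mismatch");
  if (k <= 0 || k >= nt) stop("invalid k");
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    // max-heap of (distance, label) keeping the k smallest distances
    std::priority_queue<std::pair<double, int> > heap;
    for (int j = 0; j < nt; ++j) {
      if (self_index[i] == j) continue;
      double d2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = query(i, c) - target(j, c);
        d2 += diff * diff;
      }
      if ((int)heap.size() < k) heap.push(std::make_pair(d2, labels[j]));
      else if (d2 < heap.top().first) {
        heap.pop();
        heap.push(std::make_pair(d2, labels[j]));
      }
    }
    int pos = 0, tot = (int)heap.size();
    while (!heap.empty()) {
      pos += heap.top().second;
      heap.pop();
    }
    out[i] = tot > 0 ? (double)pos / tot : NA_REAL;
  }
  return out;
}
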