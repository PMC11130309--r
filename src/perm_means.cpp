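#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// trimmed mean matching the R-side contract: ceiling(trim * n) values
// removed per tail (FP-guarded), plain mean when trimming would empty the
// vector; buf is sorted in place
static double trimmed_mean_buf(std::vector<double>& buf, double trim) {
  int n = (int)buf.size();
  if (n == 0) return NA_REAL;
  int k = (int)std::ceil(trim * n - 1e-9);
  if (2 * k >= n) k = 0;
  std::sort(buf.begin(), buf.end());
  double s = 0.0;
  for (int i = k; i < n - k; ++i) s += buf[i];
  return s / (n - 2 * k);
}

// Batched permutation trimmed means for the ligand-receptor caller.
// x: values over the union of sender+receiver cells (cells x genes);
// perm: cells x n_perm, each column a 0-based permutation of 0..n-1; the
// first n_sender entries of a permuted ordering form the sender group.
// Returns genes x n_perm trimmed means for the sender and receiver groups.
// [[Rcpp::export]]
List perm_trimmed_means_cpp(NumericMatrix x, IntegerMatrix perm,
                            int n_sender, double trim) {
  int n = x.nrow(), g = x.ncol(), B = perm.ncol();
  if (perm.nrow() != n) stop("perm must have one row per cell");
  if (n_sender <= 0 || n_sender >= n) stop("invalid sender group size");
  NumericMatrix sender(g, B), receiver(g, B);
  std::vector<double> bs((size_t)n_sender), br((size_t)(n - n_sender));
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < g; ++j) {
      for (int i = 0; i < n_sender; ++i) bs[(size_t)i] = x(perm(i, b), j);
      for (int i = n_sender; i < n; ++i) br[(size_t)(i - n_sender)] = x(perm(i, b), j);
      sender(j, b) = trimmed_mean_buf(bs, trim);
      receiver(j, b) = trimmed_mean_buf(br, trim);
    }
  }
  return List::create(_["sender"] = sender, _["receiver"] = receiver);
}
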