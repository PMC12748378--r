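#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of the mean nearest-anchor distance: each of the B
// draws takes a uniform m-subset of spots (partial Fisher-Yates using R's
// RNG) and averages the precomputed per-spot distances. Equivalent to
// permuting a gene's expression values across spots and recomputing its
// top-fraction mask, because the value multiset (hence threshold and mask
// size) is permutation-invariant.

// [[Rcpp::export(name = ".null_mean_nn")]]
NumericVector null_mean_nn(NumericVector d_min, int m, int B) {
  int n = d_min.size();
  if (m < 1 || m > n) stop("mask size out of range");
  std::vector<int> idx(n);
  std::vector<int> picked(m);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      int r = j + (int)(unif_rand() * (n - j));
      if (r >= n) r = n - 1;
      std::swap(idx[j], idx[r]);
      picked[j] = r;
      s += d_min[idx[j]];
    }
    // undo the swaps so the index pool is pristine for the next draw
    for (int j = m - 1; j >= 0; --j) std::swap(idx[j], idx[picked[j]]);
    out[b] = s / m;
  }
  return out;
}

// Same draw, returning the individual per-spot distances of `draws`
// null masks (for the secondary Mann-Whitney comparison).

// [[Rcpp::export(name = ".null_pool_nn")]]
NumericVector null_pool_nn(NumericVector d_min, int m, int draws) {
  int n = d_min.size();
  if (m < 1 || m > n) stop("mask size out of range");
  std::vector<int> idx(n);
  NumericVector out(draws * m);
  int k = 0;
  for (int b = 0; b < draws; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int j = 0; j < m; ++j) {
      int r = j + (int)(unif_rand() * (n - j));
      if (r >= n) r = n - 1;
      std::swap(idx[j], idx[r]);
      out[k++] = d_min[idx[j]];
    }
  }
  return out;
}
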