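#include <Rcpp.h>
using namespace Rcpp;

// Draw b Monte Carlo subset sums of size `subset_size` from `pool`, with or
// without replacement. Uses R's RNG stream, so results are reproducible under
// set.seed(). Without-replacement draws use a partial Fisher-Yates shuffle;
// the index permutation persists across replicates, which is harmless because
// every prefix of a uniformly shuffled permutation is a uniform subset.
// [[Rcpp::export(name = ".mc_subset_sums")]]
NumericVector mc_subset_sums(NumericVector pool, int subset_size, int b,
                             bool replace) {
  const int n = pool.size();
  if (n < 1) stop("empty pool");
  if (subset_size < 1 || (!replace && subset_size > n))
    stop("subset_size out of range");
  if (b < 1) stop("b must be >= 1");
  NumericVector out(b);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int rep = 0; rep < b; ++rep) {
    double tot = 0.0;
    if (replace) {
      for (int j = 0; j < subset_size; ++j) {
        int k = (int)(unif_rand() * n);
        if (k >= n) k = n - 1;
        tot += pool[k];
      }
    } else {
      for (int j = 0; j < subset_size; ++j) {
        int k = j + (int)(unif_rand() * (n - j));
        if (k >= n) k = n - 1;
        std::swap(idx[j], idx[k]);
        tot += pool[idx[j]];
      }
    }
    out[rep] = tot;
  }
  return out;
}
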