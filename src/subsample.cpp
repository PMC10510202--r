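#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Means of `reps` random subsamples of `size` values drawn from x, using
// R's RNG stream. Without replacement uses a partial Fisher-Yates shuffle
// whose swaps are undone after each draw, so per-rep cost is O(size).
// [[Rcpp::export]]
NumericVector cpp_subsample_means(NumericVector x, int size, int reps,
                                  bool replace) {
  int n = x.size();
  if (size < 1 || reps < 1) stop("size and reps must be >= 1");
  if (!replace && size > n) stop("size exceeds n for sampling without replacement");
  NumericVector out(reps);
  if (replace) {
    for (int r = 0; r < reps; ++r) {
      long double s = 0.0;
      for (int j = 0; j < size; ++j) {
        int k = (int)(unif_rand() * n);
        if (k >= n) k = n - 1;
        s += x[k];
      }
      out[r] = (double)(s / size);
    }
  } else {
    std::vector<double> buf(x.begin(), x.end());
    std::vector<int> swapped(size);
    for (int r = 0; r < reps; ++r) {
      long double s = 0.0;
      for (int j = 0; j < size; ++j) {
        int k = j + (int)(unif_rand() * (n - j));
        if (k >= n) k = n - 1;
        std::swap(buf[j], buf[k]);
        swapped[j] = k;
        s += buf[j];
      }
      out[r] = (double)(s / size);
      for (int j = size - 1; j >= 0; --j) std::swap(buf[j], buf[swapped[j]]);
    }
  }
  return out;
}
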