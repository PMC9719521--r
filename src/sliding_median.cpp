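#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of the k nearest neighbours in sorted order: for element i the
// window is centred (lo = i - (k-1)/2) and clipped at the ends so it
// always holds exactly k values.
// [[Rcpp::export(name = ".sliding_clipped_median")]]
NumericVector sliding_clipped_median(NumericVector v, int k) {
  int n = v.size();
  if (k > n) k = n;
  int half = (k - 1) / 2;
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    int lo = i - half;
    if (lo < 0) lo = 0;
    int hi = lo + k - 1;
    if (hi > n - 1) { hi = n - 1; lo = n - k; }
    std::copy(v.begin() + lo, v.begin() + hi + 1, buf.begin());
    int mid = k / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (k % 2 == 0) {
      // lower half's maximum completes the even-size median
      double lower = *std::max_element(buf.begin(), buf.begin() + mid);
      m = (m + lower) / 2.0;
    }
    out[i] = m;
  }
  return out;
}
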