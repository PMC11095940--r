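#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window percentile (R type-7 quantile) per ROI row.
// Centered window of `width` frames, truncated at the edges: frame t
// (0-based) uses [t - (width-1)/2, t + width/2] clamped to the trace.
// The window is kept as a sorted vector updated incrementally (one
// insertion and one erasure per frame), so each frame costs O(width)
// memmove instead of a full selection; the quantile is then read off by
// index with the standard interpolation (1-h)*x[lo] + h*x[hi].
//' @noRd
// [[Rcpp::export(name = ".slidingPercentile")]]
NumericMatrix slidingPercentile(NumericMatrix x, int width, double p) {
  const int nr = x.nrow(), nc = x.ncol();
  if (width < 1) stop("window width must be >= 1 frame");
  const int back = (width - 1) / 2, fwd = width / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> row((size_t)nc), win;
  win.reserve(width + 1);
  for (int i = 0; i < nr; ++i) {
    for (int k = 0; k < nc; ++k) row[k] = x(i, k);   // contiguous copy
    win.assign(row.begin(), row.begin() + std::min(fwd + 1, nc));
    std::sort(win.begin(), win.end());
    for (int t = 0; t < nc; ++t) {
      if (t > 0) {
        int add = t + fwd;
        if (add < nc)
          win.insert(std::lower_bound(win.begin(), win.end(), row[add]),
                     row[add]);
        int rem = t - back - 1;
        if (rem >= 0)
          win.erase(std::lower_bound(win.begin(), win.end(), row[rem]));
      }
      const int n = (int)win.size();
      if (n == 1) { out(i, t) = win[0]; continue; }
      double index = 1.0 + (n - 1) * p;     // R type 7, 1-based
      int lo = (int)std::floor(index);
      double h = index - lo;
      double xlo = win[lo - 1];
      out(i, t) = (h <= 0.0) ? xlo : (1.0 - h) * xlo + h * win[lo];
    }
  }
  return out;
}
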