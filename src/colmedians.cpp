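#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of each column of a numeric matrix. NAs propagate.
// Used on hot paths (per-sample medians across channels / RANSAC
// predictor subsets) where an R-level apply() would dominate runtime.
// [[Rcpp::export(name = ".col_medians")]]
NumericVector col_medians(const NumericMatrix& x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(p);
  std::vector<double> buf(n);
  for (int j = 0; j < p; ++j) {
    bool has_na = false;
    for (int i = 0; i < n; ++i) {
      buf[i] = x(i, j);
      if (ISNAN(buf[i])) { has_na = true; break; }
    }
    if (has_na) { out[j] = NA_REAL; continue; }
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
    double m = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = 0.5 * (m + lo);
    }
    out[j] = m;
  }
  return out;
}
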