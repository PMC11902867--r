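#include <Rcpp.h>
using namespace Rcpp;

// Mean log fraction of length-m templates within Chebyshev distance r of
// each template, self-matches included. O(N^2) pair scan with symmetry and
// early exit; the hot loop of the approximate-entropy statistic.
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n = N - m + 1;
  std::vector<int> counts(n, 1);  // self-match
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) { ++counts[i]; ++counts[j]; }
    }
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::log((double)counts[i] / n);
  return s / n;
}
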