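#include <Rcpp.h>
using namespace Rcpp;

// Template-match pair counts for sample entropy.
//
// Counts unordered template pairs (i < j) among the first N - m windows:
//   B: Chebyshev distance of the length-m templates < r
//   A: Chebyshev distance of the length-(m+1) templates < r
// Self-matches are excluded by construction; the strict "< r" comparison
// follows the definition. Both counts use the same N - m template set so
// that A/B is a proper conditional probability.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;  // templates indexed 0 .. nt-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d >= r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        // extending both templates by one sample: Chebyshev distance at
        // length m+1 is max(d, |x[i+m] - x[j+m]|), and d < r already holds
        if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
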