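#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Considers the N - m templates of lengths m and m + 1 starting at
// i = 0..N-m-1 and counts unordered pairs (i < j) whose Chebyshev distance
// is <= r at dimension m (B) and at dimension m + 1 (A). Self-matches are
// excluded by construction. Restricting both dimensions to the same
// template set follows Richman & Moorman, so SampEn = -log(A / B).
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m; // templates usable at both m and m + 1
  double A = 0.0, B = 0.0;
  if (nt < 2 || m < 1) return NumericVector::create(_["B"] = 0.0, _["A"] = 0.0);
  const double* p = &x[0];
  for (int i = 0; i < nt - 1; ++i) {
    const double xi0 = p[i];
    for (int j = i + 1; j < nt; ++j) {
      // first component checked inline: it rejects most pairs cheaply
      if (std::fabs(xi0 - p[j]) > r) continue;
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(p[i + k] - p[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(p[i + m] - p[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["B"] = B, _["A"] = A);
}
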