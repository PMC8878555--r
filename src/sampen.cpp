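#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention):
// templates start at i = 0..n-m-1 so both the m-length and (m+1)-length
// template exist for every counted index; pairs i < j only (self-matches
// excluded); Chebyshev distance with inclusive tolerance r.
// Returns c(A, B) = (m+1)-matches and m-matches as doubles.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int ntpl = n - m; // template starts: 0 .. ntpl-1
  double A = 0.0, B = 0.0;
  if (ntpl < 2) return NumericVector::create(0.0, 0.0);
  for (int i = 0; i < ntpl - 1; ++i) {
    for (int j = i + 1; j < ntpl; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
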