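#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy, PhysioNet convention:
// templates of length m and m+1 are both drawn from starting indices
// 1..(n-m) so the two counts range over the same pairs; self-matches are
// excluded and each unordered pair is counted once (i < j).
//
// Returns c(A, B): B = #pairs with Chebyshev distance <= tol over m points,
// A = #pairs additionally matching at point m+1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > tol) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= tol) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
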