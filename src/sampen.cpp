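#include <Rcpp.h>
using namespace Rcpp;

// Ordered template-match counts for sample entropy: B counts pairs of
// m-length templates within Chebyshev tolerance r, A the same at length
// m + 1; self-matches excluded. Counts ordered pairs (i, j) and (j, i),
// matching the matrix formulation.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;           // number of (m+1)-capable template starts
  double a = 0.0, b = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool okm = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { okm = false; break; }
      }
      if (!okm) continue;
      b += 2.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) a += 2.0;
    }
  }
  return NumericVector::create(a, b);
}
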