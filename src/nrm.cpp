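#include <Rcpp.h>
using namespace Rcpp;

// Tabular method for the numerator relationship matrix. Parents are 1-based
// row indices into the (topologically ordered) pedigree, 0 when unknown.
// [[Rcpp::export]]
NumericMatrix nrm_tabular(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    double asd = (s >= 0 && d >= 0) ? A(s, d) : 0.0;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += A(j, s);
      if (d >= 0) v += A(j, d);
      v *= 0.5;
      A(i, j) = v;
      A(j, i) = v;
    }
    A(i, i) = 1.0 + 0.5 * asd;
  }
  return A;
}
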