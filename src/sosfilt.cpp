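#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads in direct form II transposed, with per-section
// initial state. sos is nsec x 6: b0 b1 b2 a0 a1 a2 (a0 == 1).
// zi is nsec x 2. Returns the filtered signal; zi is not modified.
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  int nsec = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < nsec; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (int m = 0; m < n; ++m) {
      double xm = y[m];
      double ym = b0 * xm + z1;
      z1 = b1 * xm + z2 - a1 * ym;
      z2 = b2 * xm - a2 * ym;
      y[m] = ym;
    }
  }
  return y;
}
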