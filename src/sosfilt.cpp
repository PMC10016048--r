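#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad (second-order-sections) filter, direct form II transposed.
// sos: nsec x 6 matrix, rows [b0 b1 b2 1 a1 a2]. zi: nsec x 2 initial
// conditions (already scaled for the incoming signal). Filters in place order.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x,
                          NumericMatrix zi) {
  const int nsec = sos.nrow(), n = x.size();
  if (zi.nrow() != nsec || zi.ncol() != 2) stop("zi must be nsec x 2");
  NumericVector y = clone(x);
  for (int s = 0; s < nsec; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
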