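#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, y = filter(b, a, x).
// [[Rcpp::export(name = ".iir_core")]]
NumericVector iir_core(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  if (na < 1 || a[0] == 0.0) stop("a[1] must be nonzero");
  int m = std::max(nb, na);
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  for (int i = 0; i < nb; i++) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; i++) aa[i] = a[i] / a[0];
  std::vector<double> z(m, 0.0);
  NumericVector y(n);
  for (int t = 0; t < n; t++) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int i = 1; i < m; i++) z[i - 1] = bb[i] * xt - aa[i] * yt + z[i];
    y[t] = yt;
  }
  return y;
}
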