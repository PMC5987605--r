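#include <Rcpp.h>
using namespace Rcpp;

// Recursive-least-squares adaptive interference canceller.
//
// d:     desired signal (contaminated EEG), length n
// refs:  n x n_ref matrix of reference signals (EOG channels)
// m:     FIR taps per reference (current + m-1 past samples, zero-padded)
// lambda: forgetting factor, 0 < lambda <= 1
// delta: inverse-correlation initialization scale, P0 = (1/delta) * I
//
// Per sample: r = stacked lagged references; k = P r / (lambda + r' P r);
// e = d - h' r (the cleaned output); h += k e; P = (P - k r' P) / lambda.
// [[Rcpp::export(name = ".rls_core")]]
List rls_core(NumericVector d, NumericMatrix refs, int m, double lambda,
              double delta) {
  int n = d.size();
  int nref = refs.ncol();
  if (refs.nrow() != n) stop("reference length does not match signal length");
  if (m < 1) stop("taps_m must be >= 1");
  if (lambda <= 0.0 || lambda > 1.0) stop("forgetting_lambda must be in (0, 1]");
  if (delta <= 0.0) stop("init_delta must be > 0");
  int p = m * nref;

  std::vector<double> h(p, 0.0);
  std::vector<double> P(p * p, 0.0);
  for (int i = 0; i < p; i++) P[i * p + i] = 1.0 / delta;

  NumericVector cleaned(n);
  std::vector<double> r(p), Pr(p), k(p), rP(p);

  for (int t = 0; t < n; t++) {
    // regressor: for each reference, samples t, t-1, ..., t-m+1 (zero-padded)
    for (int j = 0; j < nref; j++)
      for (int l = 0; l < m; l++)
        r[j * m + l] = (t - l >= 0) ? refs(t - l, j) : 0.0;

    double rPr = 0.0;
    for (int i = 0; i < p; i++) {
      double s = 0.0;
      for (int j = 0; j < p; j++) s += P[i * p + j] * r[j];
      Pr[i] = s;
      rPr += r[i] * s;
    }
    double denom = lambda + rPr;
    for (int i = 0; i < p; i++) k[i] = Pr[i] / denom;

    double yhat = 0.0;
    for (int i = 0; i < p; i++) yhat += h[i] * r[i];
    double e = d[t] - yhat;
    cleaned[t] = e;

    for (int i = 0; i < p; i++) h[i] += k[i] * e;

    // rP = r' P (P symmetric in exact arithmetic; compute explicitly)
    for (int j = 0; j < p; j++) {
      double s = 0.0;
      for (int i = 0; i < p; i++) s += r[i] * P[i * p + j];
      rP[j] = s;
    }
    for (int i = 0; i < p; i++)
      for (int j = 0; j < p; j++)
        P[i * p + j] = (P[i * p + j] - k[i] * rP[j]) / lambda;
  }

  NumericVector hout(h.begin(), h.end());
  NumericMatrix Pout(p, p);
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++) Pout(i, j) = P[i * p + j];
  return List::create(_["cleaned"] = cleaned, _["h"] = hout, _["P"] = Pout,
                      _["n_samples"] = n);
}
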