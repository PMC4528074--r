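#include <Rcpp.h>
using namespace Rcpp;

// IIR filter in direct form II transposed with explicit initial state,
// the building block for zero-phase (forward-backward) filtering with
// steady-state edge initialisation.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int nb = b.size(), na = a.size(), m = x.size();
  const int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0), z(n - 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < n - 1 && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(m);
  for (int i = 0; i < m; ++i) {
    const double yi = bb[0] * x[i] + z[0];
    for (int j = 0; j < n - 2; ++j)
      z[j] = bb[j + 1] * x[i] + z[j + 1] - aa[j + 1] * yi;
    z[n - 2] = bb[n - 1] * x[i] - aa[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
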