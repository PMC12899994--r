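// IIR filtering in direct form II transposed with explicit initial
// state, the primitive needed for zero-phase filtering with
// steady-state edge initialization.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int n = std::max(a.size(), b.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  for (int i = 0; i < n; ++i) { bb[i] /= a0; aa[i] /= a0; }
  std::vector<double> z(n - 1, 0.0);
  for (int i = 0; i < zi.size() && i < n - 1; ++i) z[i] = zi[i];
  int N = x.size();
  NumericVector y(N);
  for (int i = 0; i < N; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int k = 0; k < n - 2; ++k) {
      z[k] = z[k + 1] + bb[k + 1] * xi - aa[k + 1] * yi;
    }
    if (n > 1) z[n - 2] = bb[n - 1] * xi - aa[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
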