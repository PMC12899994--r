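#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy (Richman-Moorman): Chebyshev distance, self-matches
// excluded, N-m templates for both lengths so every length-m template
// admits an (m+1)-extension. Returns the entropy, a capped flag (A or B
// empty -> capped at log(#template pairs)) and the raw counts.
// [[Rcpp::export]]
List sample_entropy_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;
  if (nt < 2) return List::create(_["sampen"] = NA_REAL,
                                  _["capped"] = true,
                                  _["A"] = 0.0, _["B"] = 0.0);
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  double npairs = (double)nt * (nt - 1) / 2.0;
  double cap = std::log(npairs);
  bool capped = (A == 0 || B == 0);
  double val = capped ? cap : -std::log((double)A / (double)B);
  return List::create(_["sampen"] = val, _["capped"] = capped,
                      _["A"] = (double)A, _["B"] = (double)B);
}

// Permutation entropy: Shannon entropy of ordinal-pattern frequencies
// (Lehmer-coded; ties broken by order of occurrence), normalized by
// log(order!) so the result lies in [0, 1].
// [[Rcpp::export]]
double perm_entropy_cpp(NumericVector x, int order, int delay) {
  int n = x.size();
  int np = n - (order - 1) * delay;
  if (np < 1) return NA_REAL;
  int nfact = 1;
  for (int i = 2; i <= order; ++i) nfact *= i;
  std::vector<double> counts(nfact, 0.0);
  for (int s = 0; s < np; ++s) {
    int code = 0;
    for (int i = 0; i < order; ++i) {
      int smaller = 0;
      double xi = x[s + i * delay];
      for (int j = i + 1; j < order; ++j) {
        if (x[s + j * delay] < xi) ++smaller;
      }
      int f = 1;
      for (int k = 2; k <= order - 1 - i; ++k) f *= k;
      code += smaller * f;
    }
    counts[code] += 1.0;
  }
  double H = 0.0;
  for (int c = 0; c < nfact; ++c) {
    if (counts[c] > 0) {
      double p = counts[c] / np;
      H -= p * std::log(p);
    }
  }
  return H / std::log((double)nfact);
}
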