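#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Approximate entropy ApEn(m, r, N) after Pincus: Chebyshev distance,
// self-matches included. Counts template matches for lengths m and m+1 in a
// single symmetric pass with early exit on the first out-of-tolerance
// component, which keeps the O(N^2) scan fast on long physiological series.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (n < m + 1) stop("series too short for embedding dimension m");
  const int nm = n - m + 1;   // templates of length m
  const int nm1 = n - m;      // templates of length m + 1

  std::vector<double> cm(nm, 1.0);    // self-match included
  std::vector<double> cm1(nm1, 1.0);

  const double *xp = x.begin();
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      bool match = true;
      for (int l = 0; l < m; ++l) {
        if (std::fabs(xp[i + l] - xp[j + l]) > r) { match = false; break; }
      }
      if (!match) continue;
      cm[i] += 1.0; cm[j] += 1.0;
      if (j < nm1 && std::fabs(xp[i + m] - xp[j + m]) <= r) {
        // i < j < nm1 so both are valid (m+1)-templates
        cm1[i] += 1.0; cm1[j] += 1.0;
      }
    }
  }

  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i) phi_m += std::log(cm[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i) phi_m1 += std::log(cm1[i] / nm1);
  phi_m1 /= nm1;

  return phi_m - phi_m1;
}
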