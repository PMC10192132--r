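#include <Rcpp.h>
using namespace Rcpp;

// Normalized Higuchi curve lengths L(k) for k = 1..k_max.
//
// L_m(k) = [ sum_{i=1..M} |x(m+ik) - x(m+(i-1)k)| ] * (N-1) / (M*k) / k,
// with M = floor((N-m)/k) and m = 1..k (1-based); L(k) = mean_m L_m(k).
// Returns the vector (L(1), ..., L(k_max)).
//
// [[Rcpp::export]]
NumericVector cpp_higuchi_lengths(NumericVector x, int k_max) {
  const int n = x.size();
  if (k_max < 1) stop("k_max must be >= 1");
  if (n < 2) stop("signal must have at least 2 samples");
  if (k_max >= n) stop("k_max must be smaller than the signal length");
  NumericVector L(k_max);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    for (int m = 1; m <= k; ++m) {
      const int M = (n - m) / k;
      if (M < 1) { acc = NA_REAL; break; }
      double s = 0.0;
      const double *xp = REAL(x) + (m - 1);
      for (int i = 1; i <= M; ++i)
        s += std::fabs(xp[i * k] - xp[(i - 1) * k]);
      acc += s * static_cast<double>(n - 1) /
             (static_cast<double>(M) * k) / k;
    }
    L[k - 1] = ISNA(acc) ? NA_REAL : acc / k;
  }
  return L;
}
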