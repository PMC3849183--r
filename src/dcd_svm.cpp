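#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the linear C-SVM (hinge loss), with the
// bias absorbed as an augmented constant feature (Hsieh et al. 2008).
// X is n x d (bias column included by the caller), y in {-1, +1}.
// Coordinates are visited in a deterministically shuffled order per
// sweep (xorshift PRNG with fixed seed, so fits are reproducible);
// stops when the projected-gradient range falls below eps.
// [[Rcpp::export]]
NumericVector dcd_svm_cpp(NumericMatrix X, NumericVector y, double C,
                          double eps, int max_passes) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), qii(n);
  // row-major copy for cache-friendly inner products
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Xr[(size_t)i * d + j] = X(i, j);
  NumericVector w(d);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) {
    order[i] = i;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += Xr[(size_t)i * d + j] * Xr[(size_t)i * d + j];
    qii[i] = s;
  }
  uint32_t rng = 2463534242u;  // fixed seed: deterministic fits
  auto next = [&rng]() {
    rng ^= rng << 13; rng ^= rng >> 17; rng ^= rng << 5;
    return rng;
  };
  for (int pass = 0; pass < max_passes; ++pass) {
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[next() % (i + 1)]);
    double pg_max = -1e300, pg_min = 1e300;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      const double *xi = &Xr[(size_t)i * d];
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g >= 0.0) pg = 0.0;
      else if (alpha[i] >= C && g <= 0.0) pg = 0.0;
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (std::fabs(pg) > 1e-12 && qii[i] > 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qii[i], 0.0), C);
        if (a_new != a_old) {
          double delta = (a_new - a_old) * y[i];
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max - pg_min < eps) break;
  }
  return w;
}
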