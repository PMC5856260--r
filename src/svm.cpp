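#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// L2-regularized L1-loss (hinge) linear SVM, solved in the dual by coordinate
// descent (Hsieh et al., ICML 2008). X is dense n x d and should already carry
// a bias column. Per-sample box constraints Ci implement class weighting.
// Deterministic: permutations come from a seeded Mersenne twister, not R's RNG,
// so results are identical across platforms and independent of R's RNG state.
// [[Rcpp::export]]
NumericVector cpp_svm_dcd(const NumericMatrix& X, const NumericVector& y,
                          const NumericVector& Ci, const int max_epoch,
                          const double tol, const int seed) {
  const int n = X.nrow(), d = X.ncol();
  // sample-contiguous copy of X: the solver touches one sample at a time and
  // R's column-major layout would stride by n on every feature
  std::vector<double> Xr((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      Xr[(size_t)i * d + j] = X(i, j);
  std::vector<double> w(d, 0.0), alpha(n, 0.0), Q(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    double q = 0.0;
    for (int j = 0; j < d; ++j) q += xi[j] * xi[j];
    Q[i] = q;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::mt19937 rng((uint32_t)seed);

  for (int epoch = 0; epoch < max_epoch; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (Q[i] <= 0) continue;
      const double* xi = &Xr[(size_t)i * d];
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0) PG = 0.0;
      else if (alpha[i] >= Ci[i] && G < 0) PG = 0.0;
      if (std::abs(PG) > max_pg) max_pg = std::abs(PG);
      if (PG != 0.0) {
        const double old = alpha[i];
        double a = old - G / Q[i];
        if (a < 0.0) a = 0.0;
        if (a > Ci[i]) a = Ci[i];
        alpha[i] = a;
        const double delta = (a - old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
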