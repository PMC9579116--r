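#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM,
//   min_w 0.5*||w||^2 + C * sum_i max(0, 1 - y_i * w.x_i),
// solved in the dual (Hsieh et al. 2008, "A dual coordinate descent method
// for large-scale linear SVM"). The bias is absorbed as an augmented
// constant feature supplied by the caller, so it is (weakly) regularized,
// as in liblinear's -B option.
//
// Xt: p x n matrix, one COLUMN per training example (column-major R storage
//     makes each example contiguous), already standardized & bias-augmented.
// y:  labels in {-1, +1}
// The sweep order is permuted with a small internal LCG so convergence does
// not depend on example order, while staying deterministic and leaving R's
// RNG stream untouched.
// Returns the primal weight vector w (length p).
// [[Rcpp::export]]
NumericVector svm_linear_cd(NumericMatrix Xt, NumericVector y, double C = 1.0,
                            int max_epochs = 100, double tol = 1e-3) {
  const int p = Xt.nrow(), n = Xt.ncol();
  const double *X = Xt.begin();
  std::vector<double> alpha(n, 0.0), w(p, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * p;
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long state = 88172645463325252ULL;  // fixed xorshift seed
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates with internal xorshift64 (deterministic)
    for (int i = n - 1; i > 0; --i) {
      state ^= state << 13; state ^= state >> 7; state ^= state << 17;
      int j = (int)(state % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double max_viol = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (qii[i] <= 0.0) continue;
      const double *xi = X + (size_t)i * p;
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * xi[j];
      const double g = y[i] * wx - 1.0;          // dual coordinate gradient
      double pg = g;                             // projected gradient
      if (alpha[i] <= 0.0) pg = (g < 0.0) ? g : 0.0;
      else if (alpha[i] >= C) pg = (g > 0.0) ? g : 0.0;
      const double av = std::fabs(pg);
      if (av > max_viol) max_viol = av;
      if (av > 1e-12) {
        const double old = alpha[i];
        double a = old - g / qii[i];
        if (a < 0.0) a = 0.0; else if (a > C) a = C;
        alpha[i] = a;
        const double d = (a - old) * y[i];
        if (d != 0.0) for (int j = 0; j < p; ++j) w[j] += d * xi[j];
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
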