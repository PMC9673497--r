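#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin RBF-kernel SVM trained with the simplified SMO algorithm and
// an incrementally maintained error cache (each alpha update is O(n), each
// KKT check O(1)). The full kernel matrix is precomputed (problem sizes
// here are hundreds to a few thousand samples). Randomised partner
// selection draws from R's RNG so training is reproducible under
// set.seed().

static inline double rbf(const double* xi, const double* xj, int p,
                         double gamma, int n) {
  double d = 0.0;
  for (int k = 0; k < p; ++k) {
    double t = xi[(size_t)k * n] - xj[(size_t)k * n];
    d += t * t;
  }
  return std::exp(-gamma * d);
}

// [[Rcpp::export]]
List svm_smo_train_cpp(NumericMatrix X, NumericVector y, double C,
                       double gamma, double tol = 1e-3, int max_passes = 3,
                       int max_sweeps = 60) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t)n * n);
  const double* xp = REAL(X);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double k = rbf(xp + i, xp + j, p, gamma, n);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }
  std::vector<double> alpha(n, 0.0), E(n);
  double b = 0.0;
  for (int i = 0; i < n; ++i) E[i] = -y[i];  // f = 0 initially
  int passes = 0, sweeps = 0;
  while (passes < max_passes && sweeps < max_sweeps) {
    ++sweeps;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = E[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = (int)(unif_rand() * (n - 1));
        if (j >= i) ++j;
        double Ej = E[j];
        double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        double Kij = K[(size_t)i * n + j];
        double eta = 2.0 * Kij - 2.0;  // Kii = Kjj = 1 for RBF
        if (eta >= 0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        if (aj > H) aj = H;
        if (aj < L) aj = L;
        if (std::fabs(aj - aj_old) < 1e-7) continue;
        double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        double b1 = b - Ei - y[i] * (ai - ai_old) - y[j] * (aj - aj_old) * Kij;
        double b2 = b - Ej - y[i] * (ai - ai_old) * Kij - y[j] * (aj - aj_old);
        double b_new;
        if (ai > 0 && ai < C) b_new = b1;
        else if (aj > 0 && aj < C) b_new = b2;
        else b_new = (b1 + b2) / 2.0;
        double di = y[i] * (ai - ai_old), dj = y[j] * (aj - aj_old);
        double db = b_new - b;
        const double* Ki = &K[(size_t)i * n];
        const double* Kj = &K[(size_t)j * n];
        for (int k = 0; k < n; ++k) E[k] += di * Ki[k] + dj * Kj[k] + db;
        alpha[i] = ai;
        alpha[j] = aj;
        b = b_new;
        ++changed;
      }
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["sweeps"] = sweeps);
}

// Decision values f(x) = sum_i alpha_i y_i K(x_i, x) + b for new samples.
// coef = alpha * y for the support vectors only.
// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix SV, NumericVector coef, double b,
                               double gamma, NumericMatrix Xnew) {
  int ns = SV.nrow(), p = SV.ncol(), m = Xnew.nrow();
  if (Xnew.ncol() != p) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double s = b;
    for (int i = 0; i < ns; ++i) {
      double d = 0.0;
      for (int k = 0; k < p; ++k) {
        double diff = SV(i, k) - Xnew(t, k);
        d += diff * diff;
      }
      s += coef[i] * std::exp(-gamma * d);
    }
    out[t] = s;
  }
  return out;
}
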