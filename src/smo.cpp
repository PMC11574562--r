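#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual with a
// precomputed kernel matrix. Maximal-violating-pair working-set
// selection; stops when the KKT violation gap drops below `tol`.
//
// Dual (maximization form): max sum(a) - 0.5 * sum_ij a_i a_j y_i y_j K_ij
// subject to 0 <= a_i <= C and sum_i a_i y_i = 0.
//
// Returns alpha, intercept b (decision f(x) = sum a_i y_i k(x, x_i) + b),
// the achieved dual objective, iteration count, and the final gap.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-4, int max_iter = 0) {
  int n = K.nrow();
  if (max_iter <= 0) max_iter = std::max(10000, 300 * n);
  std::vector<double> a(n, 0.0), f0(n, 0.0);

  int it = 0;
  double m = 0.0, M = 0.0;
  for (; it < max_iter; ++it) {
    // maximal violating pair over I_up / I_low; viol_i = y_i - f0_i
    int i = -1, j = -1;
    m = -1e30; M = 1e30;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - f0[t];
      bool up  = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      bool low = (y[t] < 0 && a[t] < C) || (y[t] > 0 && a[t] > 0);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    double s = y[i] * y[j];
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a[j] - a[i]);
      H = std::min(C, C + a[j] - a[i]);
    } else {
      L = std::max(0.0, a[i] + a[j] - C);
      H = std::min(C, a[i] + a[j]);
    }
    if (L >= H) continue;
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    double Ei = f0[i] - y[i], Ej = f0[j] - y[j];
    double aj_new = a[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double daj = aj_new - a[j];
    if (std::fabs(daj) < 1e-14) continue;
    double ai_new = a[i] - s * daj;
    double dai = ai_new - a[i];
    a[i] = ai_new;
    a[j] = aj_new;
    for (int t = 0; t < n; ++t) {
      f0[t] += dai * y[i] * K(t, i) + daj * y[j] * K(t, j);
    }
  }

  double b = (m + M) / 2.0;
  // objective: sum(a) - 0.5 * sum_i a_i y_i f0_i
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += a[t] - 0.5 * a[t] * y[t] * f0[t];

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = it, _["gap"] = m - M);
}
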