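#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss soft-margin linear SVM.
// Xa is the training matrix with the bias column already appended; updates
// sweep rows in fixed order, so the solution is deterministic. Returns the
// augmented weight vector (w, b).
// [[Rcpp::export(name = ".linsvm_cd")]]
NumericVector linsvm_cd(NumericMatrix Xa, NumericVector y, double C,
                        double tol, int max_pass) {
  const int n = Xa.nrow(), p = Xa.ncol();
  std::vector<double> K(static_cast<size_t>(n) * n);
  std::vector<double> qd(n), alpha(n, 0.0), g(n, -1.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += Xa(i, k) * Xa(j, k);
      s *= y[i] * y[j];
      K[i * n + j] = s;
      K[j * n + i] = s;
    }
    qd[i] = K[i * n + i];
  }
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      const double G = g[i];
      double pg = G;
      if (alpha[i] <= 0.0 && G > 0.0) pg = 0.0;
      else if (alpha[i] >= C && G < 0.0) pg = 0.0;
      const double apg = std::fabs(pg);
      if (apg > max_pg) max_pg = apg;
      if (apg > 1e-14) {
        double a_new = alpha[i] - G / qd[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        const double d = a_new - alpha[i];
        if (d != 0.0) {
          const double* Ki = &K[static_cast<size_t>(i) * n];
          for (int j = 0; j < n; ++j) g[j] += d * Ki[j];
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  NumericVector w(p);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += alpha[i] * y[i] * Xa(i, k);
    w[k] = s;
  }
  return w;
}
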