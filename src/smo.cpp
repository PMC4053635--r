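#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual solver by sequential minimal optimization with
// per-sample upper bounds C[i] (maximal-violating-pair working-set
// selection, ties resolved toward the lowest index for determinism).
// Minimizes 0.5 * a' Q a - 1' a with Q_ij = y_i y_j K_ij, subject to
// 0 <= a_i <= C_i and sum a_i y_i = 0. Indefinite kernels (e.g. tanh) are
// handled by flooring the pairwise curvature, so each update stays a
// monotone descent step; convergence is then only guaranteed within the
// iteration budget and is reported, not assumed.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector C,
               double eps = 1e-6, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n || C.size() != n)
    stop("kernel matrix, labels and caps must agree in size");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double tau = 1e-12;

  int it = 0;
  double viol = R_PosInf;
  for (it = 0; it < max_iter; ++it) {
    // working-set selection: maximal KKT violating pair
    int i = -1, j = -1;
    double gmax = -R_PosInf, gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C[t] - 1e-15) : (alpha[t] > 1e-15);
      bool lo = (y[t] > 0) ? (alpha[t] > 1e-15) : (alpha[t] < C[t] - 1e-15);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    viol = gmax - gmin;
    if (i < 0 || j < 0 || viol < eps) break;

    double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      // curvature along the feasible direction; Q_ij = y_i y_j K_ij = -K_ij here
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = tau;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > C[i] - C[j]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; }
      } else {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = tau;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C[i]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C[j]) {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = y[i] * (alpha[i] - old_ai), daj = y[j] * (alpha[j] - old_aj);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K(t, i) * dai + K(t, j) * daj);
  }

  // bias from free support vectors, else midpoint of the violation bracket
  double bsum = 0; int nfree = 0;
  double gmax = -R_PosInf, gmin = R_PosInf;
  for (int t = 0; t < n; ++t) {
    bool up = (y[t] > 0) ? (alpha[t] < C[t] - 1e-15) : (alpha[t] > 1e-15);
    bool lo = (y[t] > 0) ? (alpha[t] > 1e-15) : (alpha[t] < C[t] - 1e-15);
    double v = -y[t] * G[t];
    if (up && v > gmax) gmax = v;
    if (lo && v < gmin) gmin = v;
    if (alpha[t] > 1e-12 && alpha[t] < C[t] - 1e-12) { bsum += v; ++nfree; }
  }
  double bias = nfree > 0 ? bsum / nfree
                          : (R_finite(gmax) && R_finite(gmin) ? (gmax + gmin) / 2.0 : 0.0);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = bias,
                      _["iterations"] = it,
                      _["converged"] = viol < eps,
                      _["kkt_violation"] = viol);
}
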