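// Sequential minimal optimization for the C-SVC dual with maximal-violating-
// pair working-set selection (Keerthi et al. / LIBSVM-style first-order
// selection). The kernel matrix is precomputed on the R side; problem sizes
// here are small (hundreds of rows).

#include <Rcpp.h>
using namespace Rcpp;

// Solves: min_a 0.5 * a' Q a - e' a,  Q_ij = y_i y_j K_ij,
// subject to 0 <= a_i <= C, sum_i a_i y_i = 0.
// Returns alpha, the bias b (decision f(x) = sum_i a_i y_i K(x_i, x) + b),
// iteration count and convergence flag.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_iter = 200000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label dimension mismatch");

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // gradient of dual objective
  int iter = 0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;

  while (iter < max_iter) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double yG = -y[t] * G[t];
      const bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && yG > m_up) { m_up = yG; i = t; }
      if (in_low && yG < m_low) { m_low = yG; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) { converged = true; break; }

    // two-variable analytic update along the feasible direction
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double delta = (m_up - m_low) / quad;

    // box constraints: alpha_i moves by +y_i*delta, alpha_j by -y_j*delta
    double max_di = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double max_dj = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (delta > max_di) delta = max_di;
    if (delta > max_dj) delta = max_dj;

    const double dai = y[i] * delta;
    const double daj = -y[j] * delta;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * y[i] * K(t, i) * dai + y[t] * y[j] * K(t, j) * daj;
    }
    ++iter;
  }

  const double b = (m_up + m_low) / 2.0;

  // dual objective, for diagnostics / oracle comparison
  double obj = 0.0;
  for (int s = 0; s < n; ++s) {
    if (alpha[s] == 0.0) continue;
    obj -= alpha[s];
    for (int t = 0; t < n; ++t) {
      if (alpha[t] == 0.0) continue;
      obj += 0.5 * alpha[s] * alpha[t] * y[s] * y[t] * K(s, t);
    }
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged, _["objective"] = obj);
}
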