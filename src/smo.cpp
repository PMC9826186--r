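#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the weighted C-SVM dual
//
//   min_a  0.5 a'Qa - e'a ,  Q_ij = y_i y_j K_ij,
//   s.t.   y'a = 0,  0 <= a_i <= C_i   (per-subject box),
//
// with second-order working-set selection (maximal violator i, then the
// partner j maximizing the guaranteed objective decrease) and the standard
// m(a) - M(a) <= eps stopping rule.  Zero-box subjects (C_i = 0) never
// enter a working set, so zero-weight observations are inert.
//
// The intercept is the average of -y_i G_i over strictly interior support
// vectors (0 < a_i < C_i); when none are interior it falls back to the
// midpoint (m + M) / 2 of the KKT-feasible interval.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector C,
               double eps = 1e-5, int max_iter = 2000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n || C.size() != n)
    stop("dimension mismatch in SMO inputs");

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double *Kp = REAL(K);
  const double inf = std::numeric_limits<double>::infinity();

  int iter = 0;
  double m_val = 0.0, M_val = 0.0;
  for (; iter < max_iter; ++iter) {
    // i: maximal violator in the up-set
    int i = -1;
    double Gmax = -inf, Gmin = inf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up  = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0)    : (alpha[t] < C[t]);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) Gmin = v;
    }
    m_val = Gmax; M_val = Gmin;
    if (i < 0 || Gmax - Gmin <= eps) break;

    // j: low-set partner with the largest second-order gain
    const double *Ki = Kp + (size_t)i * n;
    int j = -1;
    double best = -inf;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C[t]);
      if (!low) continue;
      double vdiff = Gmax - (-y[t] * G[t]);
      if (vdiff <= 0) continue;
      double a = Ki[i] + Kp[(size_t)t * n + t] - 2.0 * Ki[t];
      if (a <= 0) a = 1e-12;
      double gain = vdiff * vdiff / a;
      if (gain > best) { best = gain; j = t; }
    }
    if (j < 0) break;

    const double *Kj = Kp + (size_t)j * n;
    double a = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (a <= 0) a = 1e-12;
    // step along (da_i, da_j) = (y_i t, -y_j t), t > 0
    double t_step = (Gmax - (-y[j] * G[j])) / a;
    double lim_i = (y[i] > 0) ? (C[i] - alpha[i]) : alpha[i];
    double lim_j = (y[j] > 0) ? alpha[j] : (C[j] - alpha[j]);
    if (t_step > lim_i) t_step = lim_i;
    if (t_step > lim_j) t_step = lim_j;
    if (t_step <= 0) break;  // numerically stuck at a box corner

    alpha[i] += y[i] * t_step;
    alpha[j] -= y[j] * t_step;
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C[i]) alpha[i] = C[i];
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > C[j]) alpha[j] = C[j];

    for (int s = 0; s < n; ++s)
      G[s] += y[s] * t_step * (Ki[s] - Kj[s]);
  }

  double b = 0.0; int n_int = 0;
  for (int t = 0; t < n; ++t) {
    double margin = 1e-8 * std::max(1.0, C[t]);
    if (alpha[t] > margin && alpha[t] < C[t] - margin) {
      b += -y[t] * G[t];
      ++n_int;
    }
  }
  if (n_int > 0) b /= n_int;
  else if (std::isfinite(m_val) && std::isfinite(M_val))
    b = (m_val + M_val) / 2.0;  // feasible interval is [m, M]

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["intercept"] = b,
                      _["iterations"] = iter,
                      _["kkt_gap"] = m_val - M_val,
                      _["converged"] = (m_val - M_val) <= eps);
}
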