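#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Projected gradient descent on the reparameterization gamma minimizing
//   J(gamma) = sum_i w_i |q1_i - (q2 o gamma)_i sqrt(gammadot_i)|^2
// with trapezoid weights w, stencil differentiation of gamma, endpoints
// fixed and monotonicity enforced by step rejection. Polishes the lattice
// DP solution; the analytic gradient is
//   dJ/dgamma = -2 a - D' b,
// a_i = w_i (r_i . q2'(g_i)) sqrt(gd_i), b_i = w_i (r_i . q2(g_i))/sqrt(gd_i).

static inline double interp1(const std::vector<double> &y, double pos, int n,
                             double h) {
  double u = pos / h;
  if (u <= 0) return y[0];
  if (u >= n - 1) return y[n - 1];
  int i0 = (int)std::floor(u);
  double w = u - i0;
  return (1 - w) * y[i0] + w * y[i0 + 1];
}

// stencil derivative of a vector on uniform grid
static void stencil(const std::vector<double> &y, std::vector<double> &d,
                    int n, double h) {
  for (int i = 1; i < n - 1; ++i) d[i] = (y[i + 1] - y[i - 1]) / (2 * h);
  d[0] = (-3 * y[0] + 4 * y[1] - y[2]) / (2 * h);
  d[n - 1] = (3 * y[n - 1] - 4 * y[n - 2] + y[n - 3]) / (2 * h);
}

// [[Rcpp::export(name = ".refine_gamma_cpp")]]
NumericVector refine_gamma_cpp(NumericMatrix q1, NumericMatrix q2,
                               NumericVector gamma0, int max_iter = 120,
                               double step0 = 0.1) {
  int n = q1.nrow();
  double h = 1.0 / (n - 1);
  std::vector<double> w(n, h);
  w[0] = w[n - 1] = h / 2;
  std::vector<double> q2x(n), q2y(n), q2px(n), q2py(n);
  for (int i = 0; i < n; ++i) { q2x[i] = q2(i, 0); q2y[i] = q2(i, 1); }
  stencil(q2x, q2px, n, h);
  stencil(q2y, q2py, n, h);

  std::vector<double> g(n), gtry(n), gd(n), rx(n), ry(n), a(n), b(n), grad(n);
  for (int i = 0; i < n; ++i) g[i] = gamma0[i];

  // J(gamma) with exact normalization of the warped q
  auto evalJ = [&](const std::vector<double> &gg) {
    std::vector<double> ggd(n);
    stencil(gg, ggd, n, h);
    double nrm2 = 0, dot = 0;
    std::vector<double> qgx(n), qgy(n);
    for (int i = 0; i < n; ++i) {
      double gdv = ggd[i] > 1e-8 ? ggd[i] : 1e-8;
      double s = std::sqrt(gdv);
      double p = gg[i] < 0 ? 0 : (gg[i] > 1 ? 1 : gg[i]);
      qgx[i] = interp1(q2x, p, n, h) * s;
      qgy[i] = interp1(q2y, p, n, h) * s;
      nrm2 += w[i] * (qgx[i] * qgx[i] + qgy[i] * qgy[i]);
    }
    double nrm = std::sqrt(nrm2 > 0 ? nrm2 : 1e-30);
    double J = 0;
    for (int i = 0; i < n; ++i) {
      double dx = q1(i, 0) - qgx[i] / nrm, dy = q1(i, 1) - qgy[i] / nrm;
      J += w[i] * (dx * dx + dy * dy);
    }
    return J;
  };

  double J = evalJ(g);
  double step = step0;
  for (int it = 0; it < max_iter; ++it) {
    stencil(g, gd, n, h);
    for (int i = 0; i < n; ++i) {
      double gdv = gd[i] > 1e-8 ? gd[i] : 1e-8;
      double s = std::sqrt(gdv);
      double p = g[i] < 0 ? 0 : (g[i] > 1 ? 1 : g[i]);
      double qx = interp1(q2x, p, n, h), qy = interp1(q2y, p, n, h);
      double px = interp1(q2px, p, n, h), py = interp1(q2py, p, n, h);
      rx[i] = q1(i, 0) - qx * s;
      ry[i] = q1(i, 1) - qy * s;
      a[i] = w[i] * (rx[i] * px + ry[i] * py) * s;
      b[i] = w[i] * (rx[i] * qx + ry[i] * qy) / s;
    }
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int j = 1; j < n - 1; ++j) {        // D' b, interior rows of D
      grad[j + 1] += b[j] / (2 * h);
      grad[j - 1] -= b[j] / (2 * h);
    }
    grad[0] -= 3 * b[0] / (2 * h);
    grad[1] += 4 * b[0] / (2 * h);
    grad[2] -= b[0] / (2 * h);
    grad[n - 1] += 3 * b[n - 1] / (2 * h);
    grad[n - 2] -= 4 * b[n - 1] / (2 * h);
    grad[n - 3] += b[n - 1] / (2 * h);
    for (int i = 0; i < n; ++i) grad[i] = -2 * a[i] - grad[i];
    grad[0] = grad[n - 1] = 0;

    bool ok = false;
    for (int hv = 0; hv <= 8; ++hv) {
      bool mono = true;
      for (int i = 0; i < n; ++i) gtry[i] = g[i] - step * grad[i];
      gtry[0] = 0; gtry[n - 1] = 1;
      for (int i = 1; i < n; ++i)
        if (gtry[i] - gtry[i - 1] <= 1e-9) { mono = false; break; }
      if (mono) {
        double J2 = evalJ(gtry);
        if (J2 < J - 1e-14) {
          g = gtry; J = J2; step *= 1.5; ok = true;
          break;
        }
      }
      step /= 2;
    }
    if (!ok) break;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g[i];
  return out;
}
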