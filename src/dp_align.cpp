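#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dynamic-programming alignment of two SRVF curves sampled on a uniform
// T-point grid. The reparameterization gamma is restricted to piecewise
// linear paths through the T x T lattice with local slopes dj/di drawn from
// a fixed coprime step set (di, dj in 1..max_step). Edge cost from node
// (i-di, j-dj) to (i, j) is the trapezoid approximation of
//   int |q1(t) - sqrt(gdot) q2(gamma(t))|^2 dt
// over the covered parameter interval, with q2 linearly interpolated.

static inline double q2interp(const NumericMatrix &q2, double pos, int col) {
  int n = q2.nrow();
  if (pos <= 0) return q2(0, col);
  if (pos >= n - 1) return q2(n - 1, col);
  int i0 = (int)std::floor(pos);
  double w = pos - i0;
  return (1.0 - w) * q2(i0, col) + w * q2(i0 + 1, col);
}

static int gcd(int a, int b) { while (b) { int t = a % b; a = b; b = t; } return a; }

// [[Rcpp::export(name = ".dp_align_cpp")]]
List dp_align_cpp(NumericMatrix q1, NumericMatrix q2, int max_step = 4) {
  int n = q1.nrow();
  double h = 1.0 / (n - 1);
  std::vector<std::pair<int,int> > steps;
  for (int di = 1; di <= max_step; ++di)
    for (int dj = 1; dj <= max_step; ++dj)
      if (gcd(di, dj) == 1) steps.push_back(std::make_pair(di, dj));

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> E((size_t)n * n, INF);
  std::vector<int> Pi((size_t)n * n, -1), Pj((size_t)n * n, -1);
  E[0] = 0.0;

  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = INF; int bi = -1, bj = -1;
      for (size_t s = 0; s < steps.size(); ++s) {
        int di = steps[s].first, dj = steps[s].second;
        int i0 = i - di, j0 = j - dj;
        if (i0 < 0 || j0 < 0) continue;
        double prev = E[(size_t)j0 * n + i0];
        if (!(prev < INF)) continue;
        double slope = (double)dj / (double)di;
        double sq = std::sqrt(slope);
        // trapezoid over the di+1 sample points of the edge
        double cost = 0.0;
        for (int k = 0; k <= di; ++k) {
          double w = (k == 0 || k == di) ? 0.5 : 1.0;
          double pos = j0 + slope * k;
          double dx = q1(i0 + k, 0) - sq * q2interp(q2, pos, 0);
          double dy = q1(i0 + k, 1) - sq * q2interp(q2, pos, 1);
          cost += w * (dx * dx + dy * dy);
        }
        cost *= h;
        double tot = prev + cost;
        if (tot < best) { best = tot; bi = i0; bj = j0; }
      }
      E[(size_t)j * n + i] = best;
      Pi[(size_t)j * n + i] = bi;
      Pj[(size_t)j * n + i] = bj;
    }
  }

  // backtrack from (n-1, n-1)
  std::vector<int> pi, pj;
  int ci = n - 1, cj = n - 1;
  while (ci >= 0 && cj >= 0) {
    pi.push_back(ci); pj.push_back(cj);
    int ni = Pi[(size_t)cj * n + ci], nj = Pj[(size_t)cj * n + ci];
    if (ci == 0 && cj == 0) break;
    ci = ni; cj = nj;
  }
  int m = pi.size();
  NumericVector gamma(n);
  // piecewise-linear gamma through the path nodes, evaluated on the grid
  for (int k = m - 1; k > 0; --k) {
    int ia = pi[k], ja = pj[k], ib = pi[k - 1], jb = pj[k - 1];
    for (int i = ia; i <= ib; ++i) {
      double w = (ib == ia) ? 0.0 : (double)(i - ia) / (double)(ib - ia);
      gamma[i] = (ja + w * (jb - ja)) * h;
    }
  }
  gamma[0] = 0.0; gamma[n - 1] = 1.0;
  return List::create(_["gamma"] = gamma,
                      _["cost"] = E[(size_t)(n - 1) * n + (n - 1)]);
}
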