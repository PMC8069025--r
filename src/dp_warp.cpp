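#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming elastic alignment of two square-root-slope functions
// sampled on uniform grids of equal length n over [0, 1]. Admissible
// warpings are piecewise-linear monotone lattice paths built from the step
// set supplied by the caller (rows of `steps`, each a (di, dj) pair with
// di, dj >= 1). The cost of a segment from node (i-di, j-dj) to (i, j) with
// local slope m = dj/di is the trapezoid-free Riemann sum of
//   (q1(t_k) - sqrt(m) * q2(g(t_k)))^2
// over the ref-grid points t_k covered by the segment. Steps are scanned in
// the given order and only a strictly smaller cost replaces the incumbent,
// so ties resolve to the earliest-listed step (the diagonal, by convention).
//
// Returns the optimal path as 1-based node indices plus its cost.

// [[Rcpp::export]]
List dp_warp_cpp(NumericVector q1, NumericVector q2, IntegerMatrix steps,
                 double band = 1.0) {
  const int n = q1.size();
  if (q2.size() != n) stop("q1 and q2 must have equal length");
  if (n < 2) stop("need at least 2 samples");
  const int ns = steps.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  const double dt = 1.0 / (n - 1);
  // Sakoe-Chiba band: nodes with |i - j| > bw are excluded (band = 1 means
  // no constraint); the diagonal endpoints always stay admissible
  const int bw = (band >= 1.0) ? n : std::max(2, (int)std::ceil(band * n));

  std::vector<double> E((size_t)n * n, INF);
  std::vector<int> pred((size_t)n * n, -1);
  E[0] = 0.0;

  std::vector<int> sdi(ns), sdj(ns);
  std::vector<double> sm_v(ns), m_v(ns);
  for (int s = 0; s < ns; ++s) {
    sdi[s] = steps(s, 0); sdj[s] = steps(s, 1);
    m_v[s] = (double)sdj[s] / (double)sdi[s];
    sm_v[s] = std::sqrt(m_v[s]);
  }
  const double* q1p = REAL(q1);
  const double* q2p = REAL(q2);

  for (int i = 1; i < n; ++i) {
    const int jlo = std::max(1, i - bw), jhi = std::min(n - 1, i + bw);
    for (int j = jlo; j <= jhi; ++j) {
      double best = INF;
      int bestp = -1;
      for (int s = 0; s < ns; ++s) {
        const int pi = i - sdi[s], pj = j - sdj[s];
        if (pi < 0 || pj < 0) continue;
        const double eprev = E[(size_t)pi * n + pj];
        if (!(eprev < best)) continue;  // cannot improve (cost >= 0)
        const double m = m_v[s], sm = sm_v[s];
        double c = 0.0;
        for (int k = pi + 1; k <= i; ++k) {
          // g stays inside [pj, j] subset of [0, n-1]: no clamping needed
          const double g = pj + m * (k - pi);
          const int lo = (int)g;
          const double w = g - lo;
          const double q2g = (lo >= n - 1) ? q2p[n - 1]
                             : q2p[lo] * (1.0 - w) + q2p[lo + 1] * w;
          const double d = q1p[k] - sm * q2g;
          c += d * d;
        }
        const double tot = eprev + c * dt;
        if (tot < best) { best = tot; bestp = s; }
      }
      E[(size_t)i * n + j] = best;
      pred[(size_t)i * n + j] = bestp;
    }
  }
  if (!std::isfinite(E[(size_t)(n - 1) * n + (n - 1)]) && bw < n)
    stop("no path within the warping band; widen `band`");

  const double cost = E[(size_t)(n - 1) * n + (n - 1)];
  if (!std::isfinite(cost)) stop("no admissible warping path reaches the corner");

  // backtrack
  std::vector<int> pi_v, pj_v;
  int i = n - 1, j = n - 1;
  pi_v.push_back(i + 1); pj_v.push_back(j + 1);
  while (i > 0 || j > 0) {
    const int s = pred[(size_t)i * n + j];
    if (s < 0) stop("corrupt predecessor table");
    i -= steps(s, 0);
    j -= steps(s, 1);
    pi_v.push_back(i + 1); pj_v.push_back(j + 1);
  }
  std::reverse(pi_v.begin(), pi_v.end());
  std::reverse(pj_v.begin(), pj_v.end());

  return List::create(_["i"] = wrap(pi_v), _["j"] = wrap(pj_v),
                      _["cost"] = cost);
}
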