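#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 2-D phase unwrapping by reliability sorting (Herraez-style).
// Pixels are joined group-wise along edges ordered by reliability; each
// merge adds the integer multiple of 2*pi that makes the edge continuous.
// The result is congruent to the input modulo 2*pi at every pixel.

static inline double wrap_pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  return x - TWO_PI * std::floor((x + M_PI) / TWO_PI);
}

struct Edge {
  int p, q;       // pixel indices (column-major)
  double rel;     // higher = more reliable
};

// [[Rcpp::export(name = ".unwrap2d_cpp")]]
NumericMatrix unwrap2d_cpp(NumericMatrix phase) {
  const int nr = phase.nrow(), nc = phase.ncol();
  const int n = nr * nc;
  const double TWO_PI = 2.0 * M_PI;

  // pixel reliability: inverse of local second-difference magnitude
  std::vector<double> rel(n, 0.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int p = j * nr + i;
      if (i > 0 && i < nr - 1 && j > 0 && j < nc - 1) {
        double H  = wrap_pi(phase(i - 1, j) - phase(i, j)) -
                    wrap_pi(phase(i, j) - phase(i + 1, j));
        double V  = wrap_pi(phase(i, j - 1) - phase(i, j)) -
                    wrap_pi(phase(i, j) - phase(i, j + 1));
        double D1 = wrap_pi(phase(i - 1, j - 1) - phase(i, j)) -
                    wrap_pi(phase(i, j) - phase(i + 1, j + 1));
        double D2 = wrap_pi(phase(i - 1, j + 1) - phase(i, j)) -
                    wrap_pi(phase(i, j) - phase(i + 1, j - 1));
        double D = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
        rel[p] = 1.0 / (D + 1e-12);
      } else {
        rel[p] = 0.0;  // border pixels joined last
      }
    }
  }

  std::vector<Edge> edges;
  edges.reserve(2 * n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int p = j * nr + i;
      if (i + 1 < nr) edges.push_back({p, p + 1, rel[p] + rel[p + 1]});
      if (j + 1 < nc) edges.push_back({p, p + nr, rel[p] + rel[p + nr]});
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.rel > b.rel; });

  // group bookkeeping: id, member linked list, per-pixel 2*pi count
  std::vector<int> group(n), next(n, -1), head(n), tail(n), size(n, 1);
  std::vector<int> k(n, 0);
  for (int p = 0; p < n; ++p) { group[p] = p; head[p] = p; tail[p] = p; }

  const double* ph = phase.begin();
  for (const Edge& e : edges) {
    int gp = group[e.p], gq = group[e.q];
    if (gp == gq) continue;
    // ensure gp is the larger group; merge gq into gp
    int p = e.p, q = e.q;
    if (size[gp] < size[gq]) { std::swap(gp, gq); std::swap(p, q); }
    double up = ph[p] + TWO_PI * k[p];
    double uq = ph[q] + TWO_PI * k[q];
    double d  = up - uq + wrap_pi(uq - up);   // continuity target offset
    int shift = (int)std::lround(d / TWO_PI);
    if (shift != 0)
      for (int m = head[gq]; m != -1; m = next[m]) k[m] += shift;
    for (int m = head[gq]; m != -1; m = next[m]) group[m] = gp;
    next[tail[gp]] = head[gq];
    tail[gp] = tail[gq];
    size[gp] += size[gq];
  }

  NumericMatrix out(nr, nc);
  for (int p = 0; p < n; ++p) out[p] = ph[p] + TWO_PI * k[p];
  return out;
}
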