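#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Minimum-cost linear assignment by the Hungarian algorithm with row/column
// potentials, O(n^3).  cost is a square matrix; returns, for each row, the
// 1-based column assigned to it.  Ties between equal-cost assignments are
// resolved deterministically by scan order.
// [[Rcpp::export]]
IntegerVector solve_assignment(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else          minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) ans[p[j] - 1] = j;
  return ans;
}

// Minimum-image displacement for a batch of raw displacement vectors d (m x 3)
// under lattice vectors given as the rows of box (3 x 3), with boxinv its
// inverse.  Fractional coordinates are rounded to the nearest lattice point
// and the result refined over the 27 surrounding images, which is exact for
// the reduced (GROMACS-convention) triclinic cells used throughout.
// [[Rcpp::export]]
NumericMatrix min_image_cpp(NumericMatrix d, NumericMatrix box, NumericMatrix boxinv) {
  int m = d.nrow();
  NumericMatrix out(m, 3);
  // orthorhombic fast path: per-axis rounding is exact
  bool ortho = true;
  for (int i = 0; i < 3 && ortho; ++i)
    for (int j = 0; j < 3; ++j)
      if (i != j && box(i, j) != 0.0) { ortho = false; break; }
  if (ortho) {
    const double L0 = box(0, 0), L1 = box(1, 1), L2 = box(2, 2);
    for (int r = 0; r < m; ++r) {
      out(r, 0) = d(r, 0) - L0 * std::round(d(r, 0) / L0);
      out(r, 1) = d(r, 1) - L1 * std::round(d(r, 1) / L1);
      out(r, 2) = d(r, 2) - L2 * std::round(d(r, 2) / L2);
    }
    return out;
  }
  for (int r = 0; r < m; ++r) {
    double s[3];
    for (int k = 0; k < 3; ++k)
      s[k] = d(r, 0) * boxinv(0, k) + d(r, 1) * boxinv(1, k) + d(r, 2) * boxinv(2, k);
    double s0[3];
    for (int k = 0; k < 3; ++k) s0[k] = s[k] - std::round(s[k]);
    double best = INFINITY, bx = 0, by = 0, bz = 0;
    for (int i = -1; i <= 1; ++i)
      for (int j = -1; j <= 1; ++j)
        for (int k = -1; k <= 1; ++k) {
          double f0 = s0[0] + i, f1 = s0[1] + j, f2 = s0[2] + k;
          double x = f0 * box(0, 0) + f1 * box(1, 0) + f2 * box(2, 0);
          double y = f0 * box(0, 1) + f1 * box(1, 1) + f2 * box(2, 1);
          double z = f0 * box(0, 2) + f1 * box(1, 2) + f2 * box(2, 2);
          double n2 = x * x + y * y + z * z;
          if (n2 < best) { best = n2; bx = x; by = y; bz = z; }
        }
    out(r, 0) = bx; out(r, 1) = by; out(r, 2) = bz;
  }
  return out;
}
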