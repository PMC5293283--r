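// Kraskov-Stoegbauer-Grassberger (variant 1) k-nearest-neighbour mutual
// information with Chebyshev (max-norm) distances, natural log units.
// Brute-force O(F^2) neighbour search: exact, cache-friendly, and fast
// enough at the sample sizes used for per-pair atomic fluctuations.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline double cheb(const double* a, const double* b, int d, int stride) {
  // rows of an R matrix: stride = nrow between consecutive columns
  double m = 0.0;
  for (int c = 0; c < d; ++c) {
    double v = std::fabs(a[c * stride] - b[c * stride]);
    if (v > m) m = v;
  }
  return m;
}

// Core estimator on column blocks [x0, x0+dx) and [y0, y0+dy) of `m`.
// Returns NA_REAL when the k-th joint neighbour distance is exactly zero
// for any point (duplicate points), which the R wrapper handles per config.
static double ksg_core(const NumericMatrix& m, int x0, int dx, int y0, int dy, int k) {
  const int F = m.nrow();
  const double* base = &m(0, 0);
  const int stride = F;
  std::vector<double> dj(F);
  double acc = 0.0;
  for (int i = 0; i < F; ++i) {
    const double* xi = base + x0 * stride + i;
    const double* yi = base + y0 * stride + i;
    for (int j = 0; j < F; ++j) {
      if (j == i) { dj[j] = R_PosInf; continue; }
      const double* xj = base + x0 * stride + j;
      const double* yj = base + y0 * stride + j;
      double dxv = cheb(xi, xj, dx, stride);
      double dyv = cheb(yi, yj, dy, stride);
      dj[j] = dxv > dyv ? dxv : dyv;
    }
    std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.end());
    double eps = dj[k - 1];
    if (eps <= 0.0) return NA_REAL;
    int nx = 0, ny = 0;
    for (int j = 0; j < F; ++j) {
      if (j == i) continue;
      const double* xj = base + x0 * stride + j;
      if (cheb(xi, xj, dx, stride) < eps) ++nx;
      const double* yj = base + y0 * stride + j;
      if (cheb(yi, yj, dy, stride) < eps) ++ny;
    }
    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)F) - acc / F;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix xy, int dx, int dy, int k) {
  if (xy.nrow() <= k + 1) stop("need more than k + 1 samples");
  return ksg_core(xy, 0, dx, dx, dy, k);
}

// MI for every atom pair from a displacement matrix (F x 3N, atom a in
// columns 3a..3a+2). Single computation per unordered pair, mirrored.
// [[Rcpp::export]]
NumericMatrix ksg_mi_pairs_cpp(NumericMatrix disp, int natoms, int k) {
  if (disp.ncol() != 3 * natoms) stop("displacement width must be 3 * natoms");
  NumericMatrix out(natoms, natoms);
  for (int a = 0; a < natoms; ++a) {
    for (int b = a + 1; b < natoms; ++b) {
      double mi = ksg_core(disp, 3 * a, 3, 3 * b, 3, k);
      out(a, b) = mi;
      out(b, a) = mi;
    }
  }
  return out;
}
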