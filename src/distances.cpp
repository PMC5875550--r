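#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Finite sentinel for "no seed": keeps parabola intersections finite while
// sqrt(INF_D) still dwarfs any physical grid extent in mm.
static const double INF_D = 1e18;
static const double REAL_INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope),
// sample positions x_i = i * w with physical step w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double w,
                 int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -REAL_INF;
  z[1] = REAL_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      const double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = REAL_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel center to the nearest seed voxel
// center, on an axis-aligned grid with anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector seed, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = seed[i] ? 0.0 : INF_D;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k = 0; k < nz; ++k)          // pass along x
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, spacing[0], nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  for (int k = 0; k < nz; ++k)          // pass along y
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * nx * ny;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, spacing[1], ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  for (int j = 0; j < ny; ++j)          // pass along z
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * nx;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, v, z, spacing[2], nz);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Directed nearest-neighbor distances: for each row of `ref`, the minimum
// Euclidean distance to any row of `target`. Exact (all-pairs minimum).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix ref, NumericMatrix target) {
  const int n = ref.nrow(), m = target.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = ref(i, 0), y = ref(i, 1), z = ref(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = x - target(j, 0), dy = y - target(j, 1), dz = z - target(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
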