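#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform.
// f holds squared distances (in mm^2); w is the sample spacing (mm).
static void dt1d(std::vector<double> &f, int n, double w,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      double qq = (double)q * w, vv = (double)v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * w;
    while (z[k + 1] < qq) ++k;
    double diff = qq - (double)v[k] * w;
    d[q] = diff * diff + f[v[k]];
  }
}

// Exact anisotropic 3-D Euclidean distance (mm) from every voxel centre to
// the nearest TRUE voxel centre of `mask`. Voxels inside the mask get 0.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  // large finite sentinel: keeps the parabola-intersection arithmetic finite
  const double BIG = 1e20;
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = std::sqrt(d[k]);
    }
  out.attr("dim") = dims;
  return out;
}
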