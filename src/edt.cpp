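#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Large finite sentinel for "no feature yet"; keeps the parabola
// intersection arithmetic finite. Any true squared distance in a scanned
// volume is many orders of magnitude below it, so results are exact
// wherever a feature voxel exists.
static const double BIG = 1e30;

// Felzenszwalb-Huttenlocher 1D squared distance transform on samples at
// positions q*h (h = physical spacing along the scanned axis).
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double xq = q * h;
    double s;
    for (;;) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        k--;  // z[0] = -Inf guarantees k never goes below 0
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * h;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance (in physical units) from every
// voxel to the nearest feature voxel. feature is a logical volume in x-fastest
// (column-major) order.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* g = REAL(out);
  for (R_xlen_t i = 0; i < out.size(); i++)
    g[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  std::vector<double> f(nmax), d(nmax);

  // pass along x
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      double* row = g + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
      dt1d(row, d.data(), nx, spacing[0], v, z);
      std::copy(d.begin(), d.begin() + nx, row);
    }
  // pass along y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      for (int ky = 0; ky < ny; ky++)
        f[ky] = g[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int ky = 0; ky < ny; ky++)
        g[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)] = d[ky];
    }
  // pass along z
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      for (int kz = 0; kz < nz; kz++)
        f[kz] = g[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int kz = 0; kz < nz; kz++)
        g[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)] = d[kz];
    }
  return out;
}
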