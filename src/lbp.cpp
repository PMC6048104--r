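#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample in the (axis_a, axis_b) plane through voxel (x,y,z), with
// the third coordinate fixed. Coordinates are clamped (edge replication).
static double sample_plane(const double* vol, int nx, int ny, int nz,
                           int x, int y, int z, int axa, int axb,
                           double da, double db) {
  double c[3] = { (double)x, (double)y, (double)z };
  c[axa] += da;
  c[axb] += db;
  int i0[3], i1[3];
  double fr[3];
  int n[3] = { nx, ny, nz };
  for (int a = 0; a < 3; a++) {
    double cf = std::floor(c[a]);
    double f = c[a] - cf;
    // snap near-integer coordinates so exact-neighbor samples stay exact
    if (f < 1e-9) f = 0.0;
    if (f > 1.0 - 1e-9) { f = 0.0; cf += 1.0; }
    int lo = (int)cf;
    i0[a] = clampi(lo, 0, n[a] - 1);
    i1[a] = clampi(lo + 1, 0, n[a] - 1);
    fr[a] = f;
  }
  double acc = 0.0;
  for (int bx = 0; bx < 2; bx++)
    for (int by = 0; by < 2; by++)
      for (int bz = 0; bz < 2; bz++) {
        double w = (bx ? fr[0] : 1.0 - fr[0]) *
                   (by ? fr[1] : 1.0 - fr[1]) *
                   (bz ? fr[2] : 1.0 - fr[2]);
        if (w == 0.0) continue;
        int xx = bx ? i1[0] : i0[0];
        int yy = by ? i1[1] : i0[1];
        int zz = bz ? i1[2] : i0[2];
        acc += w * vol[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
      }
  return acc;
}

// Per-voxel 2D LBP codes on one orthogonal plane.
// plane: 0 = XY (axes x,y), 1 = XZ (axes x,z), 2 = YZ (axes y,z).
// P sampling points on the ellipse (ra*cos(2*pi*k/P), rb*sin(2*pi*k/P)) in
// plane coordinates, bilinear interpolation, edge replication. Bit k is set
// when the sampled gray value is >= the center value.
// [[Rcpp::export]]
IntegerVector cpp_lbp_codes(NumericVector vol, IntegerVector dims, int P,
                            double ra, double rb, int plane) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(vol);
  IntegerVector out((R_xlen_t)nx * ny * nz);
  int axa, axb;
  if (plane == 0)      { axa = 0; axb = 1; }
  else if (plane == 1) { axa = 0; axb = 2; }
  else                 { axa = 1; axb = 2; }
  std::vector<double> da(P), db(P);
  for (int k = 0; k < P; k++) {
    double th = 2.0 * M_PI * k / P;
    da[k] = ra * std::cos(th);
    db[k] = rb * std::sin(th);
    if (std::fabs(da[k]) < 1e-12) da[k] = 0.0;
    if (std::fabs(db[k]) < 1e-12) db[k] = 0.0;
  }
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++, idx++) {
        double gc = v[idx];
        int code = 0;
        for (int k = 0; k < P; k++) {
          double gp = sample_plane(v, nx, ny, nz, x, y, z, axa, axb,
                                   da[k], db[k]);
          if (gp - gc >= 0.0) code |= (1 << k);
        }
        out[idx] = code;
      }
  return out;
}

// Mean cumulative histogram of codes pooled over a wx*wy*wz window (edge
// replication via coordinate clamping) across the voxels in idx (1-based,
// x-fastest linear indices). ncodes = number of distinct codes (2^P).
// [[Rcpp::export]]
NumericVector cpp_mean_cumhist(IntegerVector codes, IntegerVector dims,
                               int wx, int wy, int wz, IntegerVector idx,
                               int ncodes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int rx = wx / 2, ry = wy / 2, rz = wz / 2;
  const double nwin = (double)wx * wy * wz;
  std::vector<double> hist(ncodes), acc(ncodes, 0.0);
  for (R_xlen_t ii = 0; ii < idx.size(); ii++) {
    R_xlen_t lin = (R_xlen_t)idx[ii] - 1;
    int x = lin % nx;
    int y = (lin / nx) % ny;
    int z = lin / ((R_xlen_t)nx * ny);
    std::fill(hist.begin(), hist.end(), 0.0);
    for (int dz = -rz; dz <= rz; dz++) {
      int zz = clampi(z + dz, 0, nz - 1);
      for (int dy = -ry; dy <= ry; dy++) {
        int yy = clampi(y + dy, 0, ny - 1);
        R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        for (int dx = -rx; dx <= rx; dx++) {
          int xx = clampi(x + dx, 0, nx - 1);
          hist[codes[base + xx]] += 1.0;
        }
      }
    }
    double cum = 0.0;
    for (int k = 0; k < ncodes; k++) {
      cum += hist[k] / nwin;
      acc[k] += cum;
    }
  }
  NumericVector out(ncodes);
  for (int k = 0; k < ncodes; k++) out[k] = acc[k] / (double)idx.size();
  return out;
}

// L1 Wasserstein distance between each idx voxel's windowed cumulative code
// histogram and each reference cumulative histogram (columns of h0mat):
// sum over codes of absolute CDF differences, i.e. 1D Wasserstein-1 in bin
// units. Returns an idx x nref matrix; the window histogram is built once
// per voxel regardless of the number of references.
// [[Rcpp::export]]
NumericMatrix cpp_window_wd(IntegerVector codes, IntegerVector dims,
                            int wx, int wy, int wz, NumericMatrix h0mat,
                            IntegerVector idx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int rx = wx / 2, ry = wy / 2, rz = wz / 2;
  const int ncodes = h0mat.nrow();
  const int nref = h0mat.ncol();
  const double nwin = (double)wx * wy * wz;
  std::vector<double> hist(ncodes);
  NumericMatrix out(idx.size(), nref);
  std::vector<double> wd(nref);
  for (R_xlen_t ii = 0; ii < idx.size(); ii++) {
    R_xlen_t lin = (R_xlen_t)idx[ii] - 1;
    int x = lin % nx;
    int y = (lin / nx) % ny;
    int z = lin / ((R_xlen_t)nx * ny);
    std::fill(hist.begin(), hist.end(), 0.0);
    for (int dz = -rz; dz <= rz; dz++) {
      int zz = clampi(z + dz, 0, nz - 1);
      for (int dy = -ry; dy <= ry; dy++) {
        int yy = clampi(y + dy, 0, ny - 1);
        R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        for (int dx = -rx; dx <= rx; dx++) {
          int xx = clampi(x + dx, 0, nx - 1);
          hist[codes[base + xx]] += 1.0;
        }
      }
    }
    double cum = 0.0;
    std::fill(wd.begin(), wd.end(), 0.0);
    for (int k = 0; k < ncodes; k++) {
      cum += hist[k] / nwin;
      for (int r = 0; r < nref; r++)
        wd[r] += std::fabs(cum - h0mat(k, r));
    }
    for (int r = 0; r < nref; r++) out(ii, r) = wd[r];
  }
  return out;
}
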