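#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Largest 6-connected foreground component of a binary mask, with fully
// enclosed background cavities filled (background components that do not
// touch the volume border). Used between graph-cut iterations to keep the
// evolving shape a single closed surface.
// [[Rcpp::export]]
LogicalVector cpp_largest_component_fill(LogicalVector mask,
                                         IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> comp(n, 0);
  const int dx[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dz[6] = { 0, 0, 0, 0, 1, -1 };

  int ncomp = 0, best = 0;
  R_xlen_t bestsize = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || comp[s]) continue;
    ncomp++;
    R_xlen_t size = 0;
    comp[s] = ncomp;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t u = q.front(); q.pop();
      size++;
      int x = u % nx, y = (u / nx) % ny, z = u / ((R_xlen_t)nx * ny);
      for (int k = 0; k < 6; k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t v = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[v] && !comp[v]) { comp[v] = ncomp; q.push(v); }
      }
    }
    if (size > bestsize) { bestsize = size; best = ncomp; }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = comp[i] == best && best > 0;

  // flood the exterior background from the border; unreached background
  // voxels are cavities -> fill
  std::vector<char> ext(n, 0);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 &&
            z != nz - 1)
          continue;
        R_xlen_t u = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!out[u] && !ext[u]) { ext[u] = 1; q.push(u); }
      }
  while (!q.empty()) {
    R_xlen_t u = q.front(); q.pop();
    int x = u % nx, y = (u / nx) % ny, z = u / ((R_xlen_t)nx * ny);
    for (int k = 0; k < 6; k++) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t v = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!out[v] && !ext[v]) { ext[v] = 1; q.push(v); }
    }
  }
  for (R_xlen_t i = 0; i < n; i++)
    if (!out[i] && !ext[i]) out[i] = true;
  return out;
}
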