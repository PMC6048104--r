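#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
#include <limits>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Spin-image-like descriptors: for each voxel in idx (1-based x-fastest
// linear index), every voxel q in the discrete ball of radius r (voxel
// units, edge replication) contributes
//   exp(-(d - d_b)^2 / (2*sigma_d^2)) * exp(-(i - i_b)^2 / (2*sigma_i^2))
// to bin (d_b, i_b). d = ||q - p|| mapped linearly from [0, r] to [0, nbd);
// intensity is min-max normalized inside the patch to [0, nbi) (degenerate
// range: intensity coordinate fixed at the center of bin 0). Bin centers sit
// at 0.5, 1.5, ... in both axes. Each descriptor is normalized to unit mass.
// Returns an n x (nbd*nbi) matrix, distance axis fastest.
// [[Rcpp::export]]
NumericMatrix cpp_spin(NumericVector vol, IntegerVector dims, IntegerVector idx,
                       int r, int nbd, int nbi, double sigma_d,
                       double sigma_i) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(vol);

  // precompute ball offsets, their distance coordinate, and the (fixed)
  // distance-axis kernel weights
  std::vector<int> ox, oy, oz;
  std::vector<double> dco;
  for (int dz = -r; dz <= r; dz++)
    for (int dy = -r; dy <= r; dy++)
      for (int dx = -r; dx <= r; dx++) {
        double d = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        if (d <= (double)r) {
          ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
          dco.push_back(d / (double)r * (double)nbd);
        }
      }
  const int noff = (int)ox.size();
  std::vector<double> wd((size_t)noff * nbd);
  const double inv2sd = 1.0 / (2.0 * sigma_d * sigma_d);
  for (int o = 0; o < noff; o++)
    for (int b = 0; b < nbd; b++) {
      double diff = dco[o] - (b + 0.5);
      wd[(size_t)o * nbd + b] = std::exp(-diff * diff * inv2sd);
    }

  const double inv2si = 1.0 / (2.0 * sigma_i * sigma_i);
  NumericMatrix out(idx.size(), nbd * nbi);
  std::vector<double> vals(noff);
  std::vector<double> h((size_t)nbd * nbi);
  std::vector<double> wi(nbi);

  for (R_xlen_t ii = 0; ii < idx.size(); ii++) {
    R_xlen_t lin = (R_xlen_t)idx[ii] - 1;
    int x = lin % nx;
    int y = (lin / nx) % ny;
    int z = lin / ((R_xlen_t)nx * ny);
    double vmin = std::numeric_limits<double>::infinity();
    double vmax = -vmin;
    for (int o = 0; o < noff; o++) {
      int xx = clampi(x + ox[o], 0, nx - 1);
      int yy = clampi(y + oy[o], 0, ny - 1);
      int zz = clampi(z + oz[o], 0, nz - 1);
      double val = v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
      vals[o] = val;
      if (val < vmin) vmin = val;
      if (val > vmax) vmax = val;
    }
    double range = vmax - vmin;
    std::fill(h.begin(), h.end(), 0.0);
    for (int o = 0; o < noff; o++) {
      double ico = (range > 0.0) ? (vals[o] - vmin) / range * (double)nbi
                                 : 0.5;  // degenerate: center of bin 0
      for (int bi = 0; bi < nbi; bi++) {
        double diff = ico - (bi + 0.5);
        wi[bi] = std::exp(-diff * diff * inv2si);
      }
      const double* wdo = &wd[(size_t)o * nbd];
      for (int bi = 0; bi < nbi; bi++) {
        double w = wi[bi];
        double* hb = &h[(size_t)bi * nbd];
        for (int bd = 0; bd < nbd; bd++) hb[bd] += wdo[bd] * w;
      }
    }
    double tot = 0.0;
    for (size_t k = 0; k < h.size(); k++) tot += h[k];
    for (size_t k = 0; k < h.size(); k++) out(ii, k) = h[k] / tot;
  }
  return out;
}

// ---- Earth Mover's Distance on a small grid with L1 ground distance ----
//
// With an L1 (city-block) ground metric the bin grid's 4-neighbor graph is a
// geodesic graph: moving mass between arbitrary bins decomposes into unit
// steps along grid edges. EMD therefore equals the minimum-cost flow that
// routes the surplus (ha - hb) over unit-cost grid edges, solved exactly by
// successive shortest paths (Bellman-Ford; the graphs have <= nr*nc + 2
// nodes).

// Flat-array min-cost-flow network whose topology (built once per grid
// shape and reused across the hundreds of thousands of per-edge calls)
// holds the 4-neighbor grid arcs plus one supply/demand arc per bin.
struct EmdNet {
  int nr = -1, nc = -1, N = 0, S = 0, T = 0;
  std::vector<int> head, nxt, first;
  std::vector<double> cap, cost;
  std::vector<int> sup_arc, dem_arc;  // arc id of S->i and i->T per bin
  std::vector<double> dist;
  std::vector<int> pe, q;
  std::vector<char> inq;

  void add(int u, int v, double w) {
    head.push_back(v); cost.push_back(w); nxt.push_back(first[u]);
    first[u] = (int)head.size() - 1;
    head.push_back(u); cost.push_back(-w); nxt.push_back(first[v]);
    first[v] = (int)head.size() - 1;
  }

  void build(int nrow, int ncol) {
    nr = nrow; nc = ncol;
    int n = nr * nc;
    S = n; T = n + 1; N = n + 2;
    head.clear(); nxt.clear(); cost.clear();
    first.assign(N, -1);
    sup_arc.assign(n, -1); dem_arc.assign(n, -1);
    for (int c = 0; c < nc; c++)
      for (int r = 0; r < nr; r++) {
        int u = r + nr * c;
        if (r + 1 < nr) { add(u, u + 1, 1.0); add(u + 1, u, 1.0); }
        if (c + 1 < nc) { add(u, u + nr, 1.0); add(u + nr, u, 1.0); }
      }
    for (int u = 0; u < n; u++) {
      add(S, u, 0.0); sup_arc[u] = (int)head.size() - 2;
      add(u, T, 0.0); dem_arc[u] = (int)head.size() - 2;
    }
    cap.assign(head.size(), 0.0);
    dist.resize(N); pe.resize(N); inq.resize(N);
  }

  double solve(const double* ha, const double* hb) {
    const double INF = std::numeric_limits<double>::infinity();
    int n = nr * nc;
    double diff = 0.0;
    for (int u = 0; u < n; u++) diff += std::fabs(ha[u] - hb[u]);
    if (diff < 1e-14) return 0.0;
    // reset residuals: grid arcs unbounded (mass <= 1), supply arcs per call
    for (int a = 0; a < (int)head.size(); a++)
      cap[a] = (a & 1) ? 0.0 : 4.0;  // forward 4 (> total mass), reverse 0
    for (int u = 0; u < n; u++) {
      double b = ha[u] - hb[u];
      cap[sup_arc[u]] = b > 0 ? b : 0.0;
      cap[sup_arc[u] + 1] = 0.0;
      cap[dem_arc[u]] = b < 0 ? -b : 0.0;
      cap[dem_arc[u] + 1] = 0.0;
    }
    double total = 0.0;
    for (;;) {
      std::fill(dist.begin(), dist.end(), INF);
      std::fill(inq.begin(), inq.end(), 0);
      q.clear();
      size_t qh = 0;
      dist[S] = 0.0; q.push_back(S); inq[S] = 1;
      pe[T] = -1;
      while (qh < q.size()) {
        int u = q[qh++];
        inq[u] = 0;
        double du = dist[u];
        for (int a = first[u]; a >= 0; a = nxt[a]) {
          if (cap[a] <= 1e-15) continue;
          int v = head[a];
          if (du + cost[a] < dist[v] - 1e-15) {
            dist[v] = du + cost[a];
            pe[v] = a;
            if (!inq[v]) { q.push_back(v); inq[v] = 1; }
          }
        }
      }
      if (!std::isfinite(dist[T])) break;
      double push = INF;
      for (int v = T; v != S; ) {
        int a = pe[v];
        push = std::min(push, cap[a]);
        v = head[a ^ 1];
      }
      for (int v = T; v != S; ) {
        int a = pe[v];
        cap[a] -= push;
        cap[a ^ 1] += push;
        total += push * cost[a];
        v = head[a ^ 1];
      }
    }
    return total;
  }
};

static double emd_grid(const double* ha, const double* hb, int nr, int nc) {
  static thread_local EmdNet net;
  if (net.nr != nr || net.nc != nc) net.build(nr, nc);
  return net.solve(ha, hb);
}

// EMD between two unit-mass histograms on an nr x nc bin grid with L1
// ground distance (row index fastest).
// [[Rcpp::export]]
double cpp_emd_l1_grid(NumericVector ha, NumericVector hb, int nr, int nc) {
  return emd_grid(REAL(ha), REAL(hb), nr, nc);
}

// EMD-based edge weights: for each row of `edges` (1-based row indices into
// the descriptor matrix `spins`), EMD between the two descriptors divided by
// dmax (the grid diameter), giving weights in [0, 1].
// [[Rcpp::export]]
NumericVector cpp_emd_weights(NumericMatrix spins, IntegerMatrix edges,
                              int nr, int nc, double dmax) {
  NumericVector out(edges.nrow());
  int nb = nr * nc;
  std::vector<double> ha(nb), hb(nb);
  for (int e = 0; e < edges.nrow(); e++) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    for (int k = 0; k < nb; k++) {
      ha[k] = spins(i, k);
      hb[k] = spins(j, k);
    }
    out[e] = emd_grid(ha.data(), hb.data(), nr, nc) / dmax;
  }
  return out;
}
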