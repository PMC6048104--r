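// Boykov-Kolmogorov max-flow / min-cut for the banded segmentation graphs.
// Terminal capacities are folded into a single residual per node
// (trcap > 0: residual edge from source, < 0: residual edge to sink); the
// constant min(cap_src, cap_snk) is added to the flow up front. Undirected
// n-links become arc pairs with equal residuals.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

struct Arc {
  int head;
  int next;     // next arc out of the same tail, -1 terminates
  double rcap;
};

const int PARENT_NONE = -1;
const int PARENT_TERMINAL = -2;
const int PARENT_ORPHAN = -3;

class BK {
 public:
  BK(int n) : first(n, -1), trcap(n, 0.0), parent(n, PARENT_NONE),
              tree(n, 0), ts(n, 0), dist(n, 0), n_(n) {}

  void add_edge(int u, int v, double cap) {
    arcs.push_back({v, first[u], cap});
    first[u] = (int)arcs.size() - 1;
    arcs.push_back({u, first[v], cap});
    first[v] = (int)arcs.size() - 1;
  }
  void add_tweights(int u, double cs, double ct) {
    double m = std::min(cs, ct);
    flow += m;
    trcap[u] += cs - ct;
  }

  double maxflow() {
    for (int i = 0; i < n_; i++) {
      if (trcap[i] > 0) { tree[i] = 1; parent[i] = PARENT_TERMINAL;
        dist[i] = 1; active.push(i); }
      else if (trcap[i] < 0) { tree[i] = 2; parent[i] = PARENT_TERMINAL;
        dist[i] = 1; active.push(i); }
    }
    time_ = 0;
    while (!active.empty()) {
      int i = active.front();
      if (tree[i] == 0 || parent[i] == PARENT_NONE) { active.pop(); continue; }
      int mid = grow(i);
      if (mid < 0) { active.pop(); continue; }
      time_++;
      augment(mid);
      adopt();
    }
    return flow;
  }

  // 1 = source side, 0 = sink side (free nodes go to the sink side)
  int side(int i) const { return tree[i] == 1 ? 1 : 0; }

 private:
  // try to grow node i's tree; returns the bridging arc (oriented S -> T)
  // or -1 when i's arcs are exhausted
  int grow(int i) {
    char t = tree[i];
    for (int a = first[i]; a >= 0; a = arcs[a].next) {
      double r = (t == 1) ? arcs[a].rcap : arcs[a ^ 1].rcap;
      if (r <= 0) continue;
      int j = arcs[a].head;
      if (tree[j] == 0) {
        tree[j] = t;
        parent[j] = a ^ 1;  // arc from j toward i
        ts[j] = ts[i];
        dist[j] = dist[i] + 1;
        active.push(j);
      } else if (tree[j] != t) {
        return (t == 1) ? a : (a ^ 1);
      } else if (ts[j] <= ts[i] && dist[j] > dist[i] + 1) {
        parent[j] = a ^ 1;  // shorter path to the terminal
        ts[j] = ts[i];
        dist[j] = dist[i] + 1;
      }
    }
    return -1;
  }

  void augment(int mid) {
    double b = arcs[mid].rcap;
    // source side: tail of mid
    for (int x = arcs[mid ^ 1].head;; ) {
      int pa = parent[x];
      if (pa == PARENT_TERMINAL) { b = std::min(b, trcap[x]); break; }
      b = std::min(b, arcs[pa ^ 1].rcap);
      x = arcs[pa].head;
    }
    // sink side: head of mid
    for (int x = arcs[mid].head;; ) {
      int pa = parent[x];
      if (pa == PARENT_TERMINAL) { b = std::min(b, -trcap[x]); break; }
      b = std::min(b, arcs[pa].rcap);
      x = arcs[pa].head;
    }
    arcs[mid].rcap -= b;
    arcs[mid ^ 1].rcap += b;
    for (int x = arcs[mid ^ 1].head;; ) {
      int pa = parent[x];
      if (pa == PARENT_TERMINAL) {
        trcap[x] -= b;
        if (trcap[x] <= 0) make_orphan(x);
        break;
      }
      arcs[pa ^ 1].rcap -= b;
      arcs[pa].rcap += b;
      if (arcs[pa ^ 1].rcap <= 0) make_orphan(x);
      x = arcs[pa].head;
    }
    for (int x = arcs[mid].head;; ) {
      int pa = parent[x];
      if (pa == PARENT_TERMINAL) {
        trcap[x] += b;
        if (trcap[x] >= 0) make_orphan(x);
        break;
      }
      arcs[pa].rcap -= b;
      arcs[pa ^ 1].rcap += b;
      if (arcs[pa].rcap <= 0) make_orphan(x);
      x = arcs[pa].head;
    }
    flow += b;
  }

  void make_orphan(int x) {
    parent[x] = PARENT_ORPHAN;
    orphans.push_back(x);
  }

  // walk to the terminal; returns the path length or -1 when the chain is
  // broken (orphan/free); stamps distances on success
  int origin_dist(int x) {
    int d = 0;
    int y = x;
    while (true) {
      if (ts[y] == time_) { d += dist[y]; break; }
      int pa = parent[y];
      if (pa == PARENT_TERMINAL) { d += 1; break; }
      if (pa == PARENT_ORPHAN || pa == PARENT_NONE) return -1;
      d++;
      y = arcs[pa].head;
    }
    // stamp the walked prefix
    int dd = d;
    for (int z = x; ts[z] != time_; ) {
      ts[z] = time_;
      dist[z] = dd--;
      int pa = parent[z];
      if (pa == PARENT_TERMINAL) break;
      z = arcs[pa].head;
    }
    return d;
  }

  void adopt() {
    while (!orphans.empty()) {
      int x = orphans.back();
      orphans.pop_back();
      if (parent[x] != PARENT_ORPHAN) continue;
      char t = tree[x];
      int best = PARENT_NONE, best_d = INT_MAX;
      for (int a = first[x]; a >= 0; a = arcs[a].next) {
        int j = arcs[a].head;
        if (tree[j] != t) continue;
        double r = (t == 1) ? arcs[a ^ 1].rcap : arcs[a].rcap;
        if (r <= 0) continue;
        int d = origin_dist(j);
        if (d >= 0 && d < best_d) { best_d = d; best = a; }
      }
      if (best != PARENT_NONE) {
        parent[x] = best;
        ts[x] = time_;
        dist[x] = best_d + 1;
      } else {
        // x leaves the tree; its tree children become orphans, and same-tree
        // neighbors with residual toward x become active
        for (int a = first[x]; a >= 0; a = arcs[a].next) {
          int j = arcs[a].head;
          if (tree[j] != t) continue;
          double r = (t == 1) ? arcs[a ^ 1].rcap : arcs[a].rcap;
          if (r > 0) active.push(j);
          int pj = parent[j];
          if (pj >= 0 && arcs[pj].head == x) make_orphan(j);
        }
        tree[x] = 0;
        parent[x] = PARENT_NONE;
      }
    }
  }

  std::vector<Arc> arcs;
  std::vector<int> first;
  std::vector<double> trcap;
  std::vector<int> parent;
  std::vector<char> tree;
  std::vector<int> ts, dist;
  std::queue<int> active;
  std::vector<int> orphans;
  double flow = 0.0;
  int n_, time_ = 0;
};

}  // namespace

// Exact s-t min-cut. tlinks: n x 2 (to-source, to-sink); edges: m x 2
// 1-based node pairs with capacities ncap (undirected). Returns the flow
// value and the source-side indicator per node.
// [[Rcpp::export]]
List cpp_bk_mincut(NumericMatrix tlinks, IntegerMatrix edges,
                   NumericVector ncap) {
  int n = tlinks.nrow();
  BK g(n);
  for (int i = 0; i < n; i++)
    g.add_tweights(i, tlinks(i, 0), tlinks(i, 1));
  for (int e = 0; e < edges.nrow(); e++)
    if (ncap[e] > 0)
      g.add_edge(edges(e, 0) - 1, edges(e, 1) - 1, ncap[e]);
  double f = g.maxflow();
  IntegerVector lab(n);
  for (int i = 0; i < n; i++) lab[i] = g.side(i);
  return List::create(Named("value") = f, Named("labels") = lab);
}
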