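// Boykov-Kolmogorov style augmenting-path max-flow for binary MRF energies.
// The graph is the standard Potts-to-cut reduction: per-node terminal
// capacities (source = cost of labeling the node S, sink = cost of labeling
// it L) and symmetric residual arcs for the pairwise penalties. Terminal
// capacities are folded into a single signed tr_cap per node, pre-pushing
// the common part of the two terminal arcs into the flow. On the graphs this
// package builds (surface-sampled point clouds with strong smoothness
// capacities) this algorithm is orders of magnitude faster than generic
// push-relabel implementations.
//
// Exactness is what the callers rely on: the search trees only terminate
// when no augmenting path remains, so the returned value is a maximum flow
// and the source tree is the source side of a minimum cut.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

const int PARENT_NONE = -3;     // no parent (free node)
const int PARENT_TERMINAL = -2; // parent is the terminal (s or t)
// any value >= 0: index of the arc from the node to its parent

struct BKGraph {
  int n;
  std::vector<int> first;  // head of per-node arc list (-1 = none)
  std::vector<int> nxt;    // next arc in list
  std::vector<int> head;   // arc target node
  std::vector<double> rcap;
  std::vector<double> tr_cap; // >0: residual from source; <0: residual to sink
  std::vector<int> parent; // parent arc id or PARENT_*
  std::vector<signed char> tag; // 0 free, 1 source tree, 2 sink tree
  std::vector<uint64_t> ts;
  std::vector<int> dist;
  std::queue<int> active;
  std::vector<char> in_active;
  std::vector<int> orphans;
  uint64_t time_now = 0;
  double flow = 0;

  BKGraph(int n_, int m_undirected) : n(n_) {
    first.assign(n, -1);
    nxt.reserve(2 * m_undirected);
    head.reserve(2 * m_undirected);
    rcap.reserve(2 * m_undirected);
    tr_cap.assign(n, 0.0);
    parent.assign(n, PARENT_NONE);
    tag.assign(n, 0);
    ts.assign(n, 0);
    dist.assign(n, 0);
    in_active.assign(n, 0);
  }

  inline int sister(int a) const { return a ^ 1; }

  void add_edge(int u, int v, double cap) {
    int a = (int)head.size();
    head.push_back(v); rcap.push_back(cap); nxt.push_back(first[u]); first[u] = a;
    head.push_back(u); rcap.push_back(cap); nxt.push_back(first[v]); first[v] = a + 1;
  }

  void set_terminal(int v, double cap_src, double cap_sink) {
    double f = cap_src < cap_sink ? cap_src : cap_sink;
    flow += f;
    tr_cap[v] = cap_src - cap_sink;
  }

  inline void make_active(int v) {
    if (!in_active[v]) { in_active[v] = 1; active.push(v); }
  }

  // residual capacity of arc a in the direction that carries flow towards
  // node `to_node` when the tree containing it is the source tree
  inline double res_to(int a) const { return rcap[a]; }

  void init() {
    for (int v = 0; v < n; ++v) {
      if (tr_cap[v] > 0) {
        tag[v] = 1; parent[v] = PARENT_TERMINAL; dist[v] = 1; ts[v] = 0;
        make_active(v);
      } else if (tr_cap[v] < 0) {
        tag[v] = 2; parent[v] = PARENT_TERMINAL; dist[v] = 1; ts[v] = 0;
        make_active(v);
      }
    }
  }

  // is v connected to a terminal through parent pointers? caches dist/ts
  bool has_origin(int v) {
    int d = 0;
    int u = v;
    while (true) {
      if (ts[u] == time_now) { d += dist[u]; break; }
      int p = parent[u];
      if (p == PARENT_TERMINAL) { d += 1; break; }
      if (p == PARENT_NONE) return false;
      d += 1;
      u = head[p];
    }
    // second pass: write back distances
    int dd = d;
    u = v;
    while (ts[u] != time_now) {
      ts[u] = time_now; dist[u] = dd;
      int p = parent[u];
      if (p == PARENT_TERMINAL || p == PARENT_NONE) break;
      dd -= 1;
      u = head[p];
    }
    return true;
  }

  void augment(int mid_arc) {
    // path: source tree side = tail of mid_arc, sink tree side = head
    int p_node = head[sister(mid_arc)];
    int q_node = head[mid_arc];
    double bottleneck = rcap[mid_arc];
    // source side: flow enters node v along sister(parent arc of v)
    for (int v = p_node;;) {
      int a = parent[v];
      if (a == PARENT_TERMINAL) { if (tr_cap[v] < bottleneck) bottleneck = tr_cap[v]; break; }
      double r = rcap[sister(a)];
      if (r < bottleneck) bottleneck = r;
      v = head[a];
    }
    // sink side: flow leaves node v along its parent arc
    for (int v = q_node;;) {
      int a = parent[v];
      if (a == PARENT_TERMINAL) { if (-tr_cap[v] < bottleneck) bottleneck = -tr_cap[v]; break; }
      double r = rcap[a];
      if (r < bottleneck) bottleneck = r;
      v = head[a];
    }
    flow += bottleneck;
    rcap[mid_arc] -= bottleneck;
    rcap[sister(mid_arc)] += bottleneck;
    for (int v = p_node;;) {
      int a = parent[v];
      if (a == PARENT_TERMINAL) {
        tr_cap[v] -= bottleneck;
        if (tr_cap[v] == 0) { parent[v] = PARENT_NONE; orphans.push_back(v); }
        break;
      }
      rcap[a] += bottleneck;
      rcap[sister(a)] -= bottleneck;
      if (rcap[sister(a)] == 0) { parent[v] = PARENT_NONE; orphans.push_back(v); }
      v = head[a];
    }
    for (int v = q_node;;) {
      int a = parent[v];
      if (a == PARENT_TERMINAL) {
        tr_cap[v] += bottleneck;
        if (tr_cap[v] == 0) { parent[v] = PARENT_NONE; orphans.push_back(v); }
        break;
      }
      rcap[sister(a)] += bottleneck;
      rcap[a] -= bottleneck;
      if (rcap[a] == 0) { parent[v] = PARENT_NONE; orphans.push_back(v); }
      v = head[a];
    }
  }

  void process_orphan(int v) {
    int best_arc = PARENT_NONE;
    int best_dist = INT32_MAX;
    signed char tv = tag[v];
    for (int a = first[v]; a != -1; a = nxt[a]) {
      // residual in the direction terminal->...->q->v (source tree) or
      // v->q->...->terminal (sink tree)
      double r = (tv == 1) ? rcap[sister(a)] : rcap[a];
      if (r <= 0) continue;
      int q = head[a];
      if (tag[q] != tv) continue;
      if (parent[q] == PARENT_NONE) continue;
      if (!has_origin(q)) continue;
      if (dist[q] < best_dist) { best_dist = dist[q]; best_arc = a; }
    }
    if (best_arc != PARENT_NONE) {
      parent[v] = best_arc;
      ts[v] = time_now;
      dist[v] = best_dist + 1;
      return;
    }
    // v leaves the tree: neighbours may adopt its children / reconnect
    for (int a = first[v]; a != -1; a = nxt[a]) {
      int q = head[a];
      if (tag[q] != tv) continue;
      int pq = parent[q];
      if (pq >= 0 && head[pq] == v) { parent[q] = PARENT_NONE; orphans.push_back(q); }
      double r = (tv == 1) ? rcap[sister(a)] : rcap[a];
      if (r > 0 && pq != PARENT_NONE) make_active(q);
    }
    tag[v] = 0;
    parent[v] = PARENT_NONE;
  }

  void adopt() {
    while (!orphans.empty()) {
      int v = orphans.back();
      orphans.pop_back();
      process_orphan(v);
    }
  }

  void run() {
    init();
    while (!active.empty()) {
      int p = active.front(); active.pop(); in_active[p] = 0;
      if (tag[p] == 0 || parent[p] == PARENT_NONE) continue;
      signed char tp = tag[p];
      for (int a = first[p]; a != -1; a = nxt[a]) {
        // growth arc: source tree grows along residual arcs p->q,
        // sink tree grows along residual arcs q->p
        double r = (tp == 1) ? rcap[a] : rcap[sister(a)];
        if (r <= 0) continue;
        int q = head[a];
        if (tag[q] == 0) {
          tag[q] = tp;
          parent[q] = sister(a); // arc q -> p
          ts[q] = ts[p];
          dist[q] = dist[p] + 1;
          make_active(q);
        } else if (tag[q] != tp) {
          // augmenting path found through arc a (oriented source->sink)
          int mid = (tp == 1) ? a : sister(a);
          ++time_now;
          augment(mid);
          adopt();
          if (tag[p] == 0 || parent[p] == PARENT_NONE) break;
          if ((tp == 1 ? rcap[a] : rcap[sister(a)]) > 0) {
            // p may still grow through this arc later
          }
          // re-examine p's arcs from scratch next round
          make_active(p);
          break;
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_bk_maxflow(int n, IntegerMatrix edges, NumericVector pairwise_cap,
                    NumericVector cap_src, NumericVector cap_sink) {
  int m = edges.nrow();
  BKGraph g(n, m);
  for (int i = 0; i < n; ++i) g.set_terminal(i, cap_src[i], cap_sink[i]);
  for (int e = 0; e < m; ++e) {
    if (pairwise_cap[e] > 0) {
      g.add_edge(edges(e, 0) - 1, edges(e, 1) - 1, pairwise_cap[e]);
    }
  }
  g.run();
  LogicalVector source_side(n);
  for (int v = 0; v < n; ++v) source_side[v] = (g.tag[v] == 1);
  return List::create(Named("flow") = g.flow,
                      Named("source_side") = source_side);
}
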