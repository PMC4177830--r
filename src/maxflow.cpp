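#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Boykov-Kolmogorov augmenting-path max-flow specialised for binary MRF
// energies on sparse pixel graphs.  Terminal edges are stored as a net
// residual per node (tr_cap > 0: residual from source; < 0: residual to
// sink).  Neighbour edges are symmetric (Potts) and stored as sister arc
// pairs 2e / 2e+1.

namespace {

const int PARENT_NONE = -1;
const int PARENT_TERMINAL = -2;
const int PARENT_ORPHAN = -3;

enum Tree : unsigned char { FREE = 0, TREE_S = 1, TREE_T = 2 };

struct BKGraph {
  int n;
  std::vector<double> tr_cap;      // net terminal residual per node
  std::vector<double> r_cap;       // residual per arc (2 per edge)
  std::vector<int> arc_head;       // head node of each arc
  std::vector<int> adj_start;      // CSR offsets into adj_arcs
  std::vector<int> adj_arcs;       // arc ids leaving each node
  std::vector<unsigned char> tree;
  std::vector<int> parent;         // parent arc (node -> parent node)
  std::queue<int> active;
  std::queue<int> orphans;

  BKGraph(int n_, const NumericVector &tr,
          const IntegerVector &eu, const IntegerVector &ev,
          const NumericVector &ecap)
      : n(n_), tr_cap(tr.begin(), tr.end()),
        tree(n_, FREE), parent(n_, PARENT_NONE) {
    const int m = eu.size();
    arc_head.resize(2 * m);
    r_cap.resize(2 * m);
    std::vector<int> deg(n, 0);
    for (int e = 0; e < m; ++e) {
      arc_head[2 * e] = ev[e];       // arc 2e: u -> v
      arc_head[2 * e + 1] = eu[e];   // arc 2e+1: v -> u
      r_cap[2 * e] = ecap[e];
      r_cap[2 * e + 1] = ecap[e];
      ++deg[eu[e]];
      ++deg[ev[e]];
    }
    adj_start.resize(n + 1, 0);
    for (int i = 0; i < n; ++i) adj_start[i + 1] = adj_start[i] + deg[i];
    adj_arcs.resize(2 * m);
    std::vector<int> fill(adj_start.begin(), adj_start.end() - 1);
    for (int e = 0; e < m; ++e) {
      adj_arcs[fill[eu[e]]++] = 2 * e;
      adj_arcs[fill[ev[e]]++] = 2 * e + 1;
    }
  }

  inline int sister(int a) const { return a ^ 1; }
  inline int tail(int a) const { return arc_head[sister(a)]; }

  // residual usable to grow tree of node i through arc a (i -> head[a])
  inline double grow_cap(int i, int a) const {
    return tree[i] == TREE_S ? r_cap[a] : r_cap[sister(a)];
  }

  // does the chain of parents from j reach a terminal?
  bool rooted(int j) const {
    while (true) {
      int p = parent[j];
      if (p == PARENT_TERMINAL) return true;
      if (p == PARENT_NONE || p == PARENT_ORPHAN) return false;
      j = arc_head[p];
    }
  }

  void set_orphan(int i) {
    parent[i] = PARENT_ORPHAN;
    orphans.push(i);
  }

  // returns boundary arc oriented S -> T, or -1 when search saturates
  int grow() {
    while (!active.empty()) {
      int i = active.front();
      if (tree[i] == FREE) { active.pop(); continue; }
      for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) {
        int a = adj_arcs[k];
        if (grow_cap(i, a) <= 0) continue;
        int j = arc_head[a];
        if (tree[j] == FREE) {
          tree[j] = tree[i];
          parent[j] = sister(a);   // arc j -> i
          active.push(j);
        } else if (tree[j] != tree[i]) {
          return tree[i] == TREE_S ? a : sister(a);
        }
      }
      active.pop();
    }
    return -1;
  }

  void augment(int m_arc) {
    int u = tail(m_arc), v = arc_head[m_arc];
    double bottleneck = r_cap[m_arc];
    for (int x = u; parent[x] != PARENT_TERMINAL; x = arc_head[parent[x]]) {
      int a = parent[x];  // x -> parent; flow travels parent -> x
      bottleneck = std::min(bottleneck, r_cap[sister(a)]);
    }
    {
      int x = u;
      while (parent[x] != PARENT_TERMINAL) x = arc_head[parent[x]];
      bottleneck = std::min(bottleneck, tr_cap[x]);
    }
    for (int x = v; parent[x] != PARENT_TERMINAL; x = arc_head[parent[x]]) {
      int a = parent[x];  // flow travels x -> parent
      bottleneck = std::min(bottleneck, r_cap[a]);
    }
    {
      int x = v;
      while (parent[x] != PARENT_TERMINAL) x = arc_head[parent[x]];
      bottleneck = std::min(bottleneck, -tr_cap[x]);
    }

    r_cap[m_arc] -= bottleneck;
    r_cap[sister(m_arc)] += bottleneck;

    int x = u;
    while (parent[x] != PARENT_TERMINAL) {
      int a = parent[x];
      r_cap[a] += bottleneck;
      r_cap[sister(a)] -= bottleneck;
      int px = arc_head[a];
      if (r_cap[sister(a)] <= 0) set_orphan(x);
      x = px;
    }
    tr_cap[x] -= bottleneck;
    if (tr_cap[x] <= 0) set_orphan(x);

    x = v;
    while (parent[x] != PARENT_TERMINAL) {
      int a = parent[x];
      r_cap[sister(a)] += bottleneck;
      r_cap[a] -= bottleneck;
      int px = arc_head[a];
      if (r_cap[a] <= 0) set_orphan(x);
      x = px;
    }
    tr_cap[x] += bottleneck;
    if (tr_cap[x] >= 0) set_orphan(x);
  }

  void adopt() {
    while (!orphans.empty()) {
      int x = orphans.front();
      orphans.pop();
      unsigned char tx = tree[x];
      int new_parent = PARENT_NONE;
      for (int k = adj_start[x]; k < adj_start[x + 1]; ++k) {
        int a = adj_arcs[k];
        int j = arc_head[a];
        if (tree[j] != tx) continue;
        double cap = tx == TREE_S ? r_cap[sister(a)] : r_cap[a];
        if (cap <= 0) continue;
        if (rooted(j)) { new_parent = a; break; }
      }
      if (new_parent != PARENT_NONE) {
        parent[x] = new_parent;
        continue;
      }
      // no parent found: free x, re-examine neighbours
      for (int k = adj_start[x]; k < adj_start[x + 1]; ++k) {
        int a = adj_arcs[k];
        int j = arc_head[a];
        if (tree[j] != tx) continue;
        double cap = tx == TREE_S ? r_cap[sister(a)] : r_cap[a];
        if (cap > 0) active.push(j);
        int pj = parent[j];
        if (pj >= 0 && arc_head[pj] == x) set_orphan(j);
      }
      tree[x] = FREE;
      parent[x] = PARENT_NONE;
    }
  }

  void run() {
    for (int i = 0; i < n; ++i) {
      if (tr_cap[i] > 0) {
        tree[i] = TREE_S;
        parent[i] = PARENT_TERMINAL;
        active.push(i);
      } else if (tr_cap[i] < 0) {
        tree[i] = TREE_T;
        parent[i] = PARENT_TERMINAL;
        active.push(i);
      }
    }
    while (true) {
      int a = grow();
      if (a < 0) break;
      augment(a);
      adopt();
    }
  }
};

}  // namespace

// Minimise sum_p theta(p, L_p) + sum_{edges} [L_u != L_v] * w_uv over binary
// labelings.  cap_source[p] = theta(p, 0), cap_sink[p] = theta(p, 1);
// returns TRUE where the minimising label is 1 (source side of the cut).
// [[Rcpp::export(name = ".bk_min_cut")]]
LogicalVector bk_min_cut(int n_nodes, NumericVector cap_source,
                         NumericVector cap_sink, IntegerVector edge_u,
                         IntegerVector edge_v, NumericVector edge_cap) {
  if (cap_source.size() != n_nodes || cap_sink.size() != n_nodes)
    stop("terminal capacity length must equal n_nodes");
  if (edge_u.size() != edge_v.size() || edge_u.size() != edge_cap.size())
    stop("edge vectors must have equal length");
  NumericVector tr(n_nodes);
  for (int i = 0; i < n_nodes; ++i) tr[i] = cap_source[i] - cap_sink[i];
  BKGraph g(n_nodes, tr, edge_u, edge_v, edge_cap);
  g.run();
  LogicalVector lab(n_nodes);
  for (int i = 0; i < n_nodes; ++i) lab[i] = g.tree[i] == TREE_S;
  return lab;
}

// Connected-component labeling of a binary matrix by BFS.
// connectivity = 4 or 8; returns integer matrix, 0 = background,
// components numbered 1..K in raster order of first pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next_label = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      lab(r, c) = next_label;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int k = 0; k < nd; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (!mask(qr, qc) || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next_label;
          stack.push_back(qr + qc * H);
        }
      }
    }
  }
  return lab;
}
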