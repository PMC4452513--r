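// Pointer-merge decomposition of a voxel shape into depth-ordered branches.
//
// Voxels are traversed in decreasing geodesic depth; an arc becomes active
// right after its second (shallower) endpoint. Every voxel starts as its
// own component pointing to itself. When an arc merges two components the
// shallower component's tip p either absorbs into the deeper tip q (its
// overhang below the junction, depth(p) - depth(u), is below the merge
// threshold) or is consolidated as a branch with fork v on the deeper
// component and parent q. Intra-component arcs are ignored (spanning-tree
// behaviour); those that do not close a local triangle are counted as
// candidate loops, since genuine loops (touching branches) join voxels
// whose neighbourhoods are otherwise disjoint.
//
// Voxel indices are assumed to be in lexicographic coordinate order, so
// index comparisons implement lexicographic tie-breaks.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct DSU {
  std::vector<int> par;
  explicit DSU(int n) : par(n) { for (int i = 0; i < n; ++i) par[i] = i; }
  int find(int x) {
    while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
    return x;
  }
};

// deeper means larger depth; equal depth resolved by smaller index
static inline bool deeper(double da, int ia, double db, int ib) {
  if (da != db) return da > db;
  return ia < ib;
}

// [[Rcpp::export(name = ".decompose_core")]]
List decompose_core(IntegerMatrix arcs, NumericVector depth, double threshold) {
  const int n = depth.size();
  const int m = arcs.nrow();

  // sort arcs by min endpoint depth descending, ties lexicographic
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::vector<double> key(m);
  std::vector<int> lo(m), hi(m);
  for (int i = 0; i < m; ++i) {
    int u = arcs(i, 0) - 1, v = arcs(i, 1) - 1;
    double du = depth[u], dv = depth[v];
    key[i] = std::min(du, dv);
    lo[i] = std::min(u, v);
    hi[i] = std::max(u, v);
  }
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (key[a] != key[b]) return key[a] > key[b];
    if (lo[a] != lo[b]) return lo[a] < lo[b];
    return hi[a] < hi[b];
  });

  // adjacency (for the triangle test on intra-component arcs)
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < m; ++i) {
    adj[arcs(i, 0) - 1].push_back(arcs(i, 1) - 1);
    adj[arcs(i, 1) - 1].push_back(arcs(i, 0) - 1);
  }
  for (int i = 0; i < n; ++i) std::sort(adj[i].begin(), adj[i].end());

  DSU dsu(n);
  std::vector<int> tip(n);           // component root -> current tip voxel
  std::vector<int> rho(n), forkv(n, -1), parent_tip(n, -1);
  for (int i = 0; i < n; ++i) { tip[i] = i; rho[i] = i; }

  int loop_count = 0;
  for (int k = 0; k < m; ++k) {
    int a = arcs(ord[k], 0) - 1, b = arcs(ord[k], 1) - 1;
    int ra = dsu.find(a), rb = dsu.find(b);
    if (ra == rb) {
      // intra-component: loop candidate if u and v share no common neighbour
      const std::vector<int>& A = adj[a];
      const std::vector<int>& B = adj[b];
      bool common = false;
      size_t i = 0, j = 0;
      while (i < A.size() && j < B.size()) {
        if (A[i] == B[j]) { common = true; break; }
        if (A[i] < B[j]) ++i; else ++j;
      }
      if (!common) ++loop_count;
      continue;
    }
    int pa = tip[ra], pb = tip[rb];
    int u, v, p, q, rp, rq;
    if (deeper(depth[pb], pb, depth[pa], pa)) {
      p = pa; q = pb; u = a; v = b; rp = ra; rq = rb;
    } else {
      p = pb; q = pa; u = b; v = a; rp = rb; rq = ra;
    }
    // p = shallower tip, u = arc endpoint in p's component,
    // v = arc endpoint in q's (deeper) component
    (void)rp;
    if (depth[p] - depth[u] < threshold) {
      rho[p] = q;                    // absorb: whole branch of p joins q
    } else {
      forkv[p] = v;                  // consolidate: p becomes a branch
      parent_tip[p] = q;
      rho[p] = q;
    }
    dsu.par[ra] = rb;
    tip[dsu.find(rb)] = q;
  }

  int root_tip = tip[dsu.find(0)];

  // resolve branch membership: follow rho to the first final tip
  // (a consolidated tip or the root tip)
  std::vector<int> branch(n, -1);
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (branch[i] >= 0) continue;
    int x = i;
    stack.clear();
    while (branch[x] < 0 && !(forkv[x] >= 0 || x == root_tip)) {
      stack.push_back(x);
      x = rho[x];
    }
    int b = (branch[x] >= 0) ? branch[x] : x;
    branch[x] = b;
    for (int s : stack) branch[s] = b;
  }

  IntegerVector branch_of(n), fork_out(n), parent_out(n);
  for (int i = 0; i < n; ++i) {
    branch_of[i] = branch[i] + 1;
    fork_out[i] = forkv[i] + 1;        // 0 when absent
    parent_out[i] = parent_tip[i] + 1; // 0 when absent
  }
  return List::create(_["branch_of"] = branch_of, _["fork"] = fork_out,
                      _["parent_tip"] = parent_out,
                      _["root_tip"] = root_tip + 1,
                      _["loop_count"] = loop_count);
}
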