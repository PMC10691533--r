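// Left-right planarity test (de Fraysseix & Rosenstiehl; Brandes'
// formulation) and the greedy planar maximally filtered graph (PMFG)
// builder that relies on it.  Vertices are 0-based; no self loops or
// parallel edges are allowed (the R wrappers enforce this).

#include <Rcpp.h>
#include <vector>
#include <algorithm>

namespace {

struct Interval {
  int low, high;  // oriented edge ids, -1 = none
  Interval() : low(-1), high(-1) {}
  bool empty() const { return low == -1 && high == -1; }
};

struct CPair {
  Interval L, R;
};

class LRPlanarity {
public:
  LRPlanarity(int n_, const std::vector<int>& eu, const std::vector<int>& ev)
      : n(n_), m((int)eu.size()), src(m, -1), dst(m, -1),
        lowpt(m, 0), lowpt2(m, 0), nest(m, 0),
        ref(m, -1), side(m, 1), lowpt_edge(m, -1), stack_bottom(m, 0),
        height(n_, -1), parent_edge(n_, -1), adj(n_), ordered(n_) {
    for (int i = 0; i < m; ++i) {
      adj[eu[i]].push_back(std::make_pair(ev[i], i));
      adj[ev[i]].push_back(std::make_pair(eu[i], i));
    }
  }

  bool run() {
    if (m == 0) return true;
    if (n >= 3 && m > 3 * n - 6) return false;
    std::vector<int> roots;
    for (int v = 0; v < n; ++v) {
      if (height[v] == -1) {
        height[v] = 0;
        roots.push_back(v);
        dfs_orient(v);
      }
    }
    // sort outgoing oriented edges by nesting depth (stable: ties by id)
    for (int i = 0; i < m; ++i) ordered[src[i]].push_back(i);
    for (int v = 0; v < n; ++v) {
      std::stable_sort(ordered[v].begin(), ordered[v].end(),
                       [&](int a, int b) { return nest[a] < nest[b]; });
    }
    for (size_t r = 0; r < roots.size(); ++r) {
      if (!dfs_test(roots[r])) return false;
    }
    return true;
  }

private:
  int n, m;
  std::vector<int> src, dst, lowpt, lowpt2, nest, ref, side, lowpt_edge,
      stack_bottom, height, parent_edge;
  std::vector<std::vector<std::pair<int, int> > > adj;  // (neighbor, edge id)
  std::vector<std::vector<int> > ordered;               // outgoing edge ids
  std::vector<CPair> S;

  void dfs_orient(int v) {
    int pe = parent_edge[v];
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k].first, id = adj[v][k].second;
      if (src[id] != -1) continue;  // already oriented
      src[id] = v;
      dst[id] = w;
      lowpt[id] = height[v];
      lowpt2[id] = height[v];
      if (height[w] == -1) {  // tree edge
        parent_edge[w] = id;
        height[w] = height[v] + 1;
        dfs_orient(w);
      } else {  // back edge
        lowpt[id] = height[w];
      }
      nest[id] = 2 * lowpt[id];
      if (lowpt2[id] < height[v]) nest[id] += 1;  // chordal
      if (pe != -1) {
        if (lowpt[id] < lowpt[pe]) {
          lowpt2[pe] = std::min(lowpt[pe], lowpt2[id]);
          lowpt[pe] = lowpt[id];
        } else if (lowpt[id] > lowpt[pe]) {
          lowpt2[pe] = std::min(lowpt2[pe], lowpt[id]);
        } else {
          lowpt2[pe] = std::min(lowpt2[pe], lowpt2[id]);
        }
      }
    }
  }

  bool conflicting(const Interval& I, int b) const {
    return !I.empty() && lowpt[I.high] > lowpt[b];
  }

  int lowest(const CPair& P) const {
    if (P.L.empty()) return lowpt[P.R.low];
    if (P.R.empty()) return lowpt[P.L.low];
    return std::min(lowpt[P.L.low], lowpt[P.R.low]);
  }

  bool add_constraints(int id, int pe) {
    CPair P;
    // merge return edges of this edge into P.R
    do {
      CPair Q = S.back();
      S.pop_back();
      if (!Q.L.empty()) std::swap(Q.L, Q.R);
      if (!Q.L.empty()) return false;  // not planar
      if (lowpt[Q.R.low] > lowpt[pe]) {
        if (P.R.empty()) P.R.high = Q.R.high;
        else ref[P.R.low] = Q.R.high;
        P.R.low = Q.R.low;
      } else {  // align
        ref[Q.R.low] = lowpt_edge[pe];
      }
    } while ((int)S.size() > stack_bottom[id]);
    // merge conflicting return edges of earlier siblings into P.L
    while (!S.empty() &&
           (conflicting(S.back().L, id) || conflicting(S.back().R, id))) {
      CPair Q = S.back();
      S.pop_back();
      if (conflicting(Q.R, id)) std::swap(Q.L, Q.R);
      if (conflicting(Q.R, id)) return false;  // not planar
      if (P.R.low != -1) ref[P.R.low] = Q.R.high;
      if (Q.R.low != -1) P.R.low = Q.R.low;
      if (P.L.empty()) P.L.high = Q.L.high;
      else ref[P.L.low] = Q.L.high;
      P.L.low = Q.L.low;
    }
    if (!(P.L.empty() && P.R.empty())) S.push_back(P);
    return true;
  }

  void trim_back_edges(int u) {
    // drop entire conflict pairs returning to u
    while (!S.empty() && lowest(S.back()) == height[u]) {
      CPair P = S.back();
      S.pop_back();
      if (P.L.low != -1) side[P.L.low] = -1;
    }
    if (!S.empty()) {  // one more pair to trim
      CPair P = S.back();
      S.pop_back();
      while (P.L.high != -1 && dst[P.L.high] == u) P.L.high = ref[P.L.high];
      if (P.L.high == -1 && P.L.low != -1) {
        ref[P.L.low] = P.R.low;
        side[P.L.low] = -1;
        P.L.low = -1;
      }
      while (P.R.high != -1 && dst[P.R.high] == u) P.R.high = ref[P.R.high];
      if (P.R.high == -1 && P.R.low != -1) {
        ref[P.R.low] = P.L.low;
        side[P.R.low] = -1;
        P.R.low = -1;
      }
      S.push_back(P);
    }
  }

  bool dfs_test(int v) {
    int pe = parent_edge[v];
    const std::vector<int>& out = ordered[v];
    for (size_t k = 0; k < out.size(); ++k) {
      int id = out[k];
      int w = dst[id];
      stack_bottom[id] = (int)S.size();
      if (id == parent_edge[w]) {  // tree edge
        if (!dfs_test(w)) return false;
      } else {  // back edge
        lowpt_edge[id] = id;
        CPair P;
        P.R.low = id;
        P.R.high = id;
        S.push_back(P);
      }
      if (lowpt[id] < height[v]) {  // has a return edge
        if (k == 0) {
          if (pe != -1) lowpt_edge[pe] = lowpt_edge[id];
        } else {
          if (!add_constraints(id, pe)) return false;
        }
      }
    }
    if (pe != -1) {  // remove back edges returning to parent
      int u = src[pe];
      trim_back_edges(u);
      if (lowpt[pe] < height[u] && !S.empty()) {
        int hl = S.back().L.high, hr = S.back().R.high;
        if (hl != -1 && (hr == -1 || lowpt[hl] > lowpt[hr])) ref[pe] = hl;
        else ref[pe] = hr;
      }
    }
    return true;
  }
};

bool planar_check(int n, const std::vector<int>& eu,
                  const std::vector<int>& ev) {
  LRPlanarity lr(n, eu, ev);
  return lr.run();
}

struct DSU {
  std::vector<int> parent, rank_, size_, edges_;
  explicit DSU(int n) : parent(n), rank_(n, 0), size_(n, 1), edges_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size_[a] += size_[b];
    edges_[a] += edges_[b];
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
};

}  // namespace

// [[Rcpp::export(name = ".lr_planar_cpp")]]
bool lr_planar_cpp(int n, Rcpp::IntegerVector u, Rcpp::IntegerVector v) {
  std::vector<int> eu(u.begin(), u.end()), ev(v.begin(), v.end());
  return planar_check(n, eu, ev);
}

// Greedy PMFG edge selection.  Candidate edges must arrive pre-sorted in
// decreasing weight order (ties already broken by the caller); returns a
// logical keep-vector.  An edge joining two components can never break
// planarity, so it is kept without a test.
// [[Rcpp::export(name = ".pmfg_cpp")]]
Rcpp::LogicalVector pmfg_cpp(int n, Rcpp::IntegerVector u,
                             Rcpp::IntegerVector v) {
  int m = u.size();
  Rcpp::LogicalVector keep(m, false);
  int kept = 0;
  std::vector<std::vector<int> > adj(n);  // kept-edge adjacency
  DSU dsu(n);
  // component extraction scratch (stamped, reused across tests)
  std::vector<int> stamp(n, -1), remap(n, -1), bfs;
  int cur = 0;
  int cap = (n >= 3) ? 3 * n - 6 : (n == 2 ? 1 : 0);
  for (int i = 0; i < m; ++i) {
    if (kept >= cap) break;
    int a = u[i], b = v[i];
    int ra = dsu.find(a), rb = dsu.find(b);
    if (ra != rb) {  // joins two components: always planar
      dsu.unite(a, b);
      dsu.edges_[dsu.find(a)] += 1;
      adj[a].push_back(b);
      adj[b].push_back(a);
      keep[i] = true;
      ++kept;
      continue;
    }
    // component already maximally planar: no further edge can fit
    if (dsu.size_[ra] >= 3 && dsu.edges_[ra] >= 3 * dsu.size_[ra] - 6) continue;
    // planarity is a per-component property: test only this component
    ++cur;
    bfs.clear();
    bfs.push_back(a);
    stamp[a] = cur;
    remap[a] = 0;
    std::vector<int> cu, cv;
    for (size_t h = 0; h < bfs.size(); ++h) {
      int x = bfs[h];
      for (size_t k = 0; k < adj[x].size(); ++k) {
        int y = adj[x][k];
        if (stamp[y] != cur) {
          stamp[y] = cur;
          remap[y] = (int)bfs.size();
          bfs.push_back(y);
        }
        if (x < y) {
          cu.push_back(remap[x]);
          cv.push_back(remap[y]);
        }
      }
    }
    cu.push_back(remap[a]);
    cv.push_back(remap[b]);
    if (planar_check((int)bfs.size(), cu, cv)) {
      keep[i] = true;
      ++kept;
      dsu.edges_[ra] += 1;
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
  }
  return keep;
}
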