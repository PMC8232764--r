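// Advancing-front triangulation of an unorganized point cloud.
//
// Greedy growth from the triangle with the smallest circumradius; a priority
// queue of candidate triangles adjacent to the open front is kept, candidates
// admitted smallest-circumradius-first and rejected when they would create a
// non-manifold or inconsistently oriented edge. On front exhaustion the
// algorithm reseeds among unused points; remaining small boundary cycles are
// closed by ear filling.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
  V3 operator-(const V3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  V3 cross(const V3& o) const {
    return {y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x};
  }
  double dot(const V3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

double circumradius(const V3& a, const V3& b, const V3& c) {
  double la = (b - c).norm(), lb = (a - c).norm(), lc = (a - b).norm();
  double area2 = (b - a).cross(c - a).norm();  // 2 * area
  if (area2 < 1e-300) return 1e300;
  return la * lb * lc / (2.0 * area2);
}

struct EdgeInfo {
  int count = 0;
  int tri[2] = {-1, -1};
  // directed usage flags: bit 0 = lo->hi used, bit 1 = hi->lo used
  int dir_used = 0;
};

struct Cand {
  double r;
  int v0, v1, v2;  // winding order
  bool operator<(const Cand& o) const {
    if (r != o.r) return r > o.r;  // min-heap
    if (v0 != o.v0) return v0 > o.v0;
    if (v1 != o.v1) return v1 > o.v1;
    return v2 > o.v2;
  }
};

struct Front {
  const std::vector<V3>& P;
  std::vector<std::vector<int>> nb;  // kNN lists
  std::unordered_map<int64_t, EdgeInfo> edges;
  std::vector<std::array<int, 3>> tris;
  std::vector<char> used;
  std::priority_queue<Cand> queue;
  double rmax, min_dot;
  int n;

  Front(const std::vector<V3>& pts, const std::vector<std::vector<int>>& knn,
        double rmax_, double min_dot_)
      : P(pts), nb(knn), rmax(rmax_), min_dot(min_dot_), n((int)pts.size()) {
    used.assign(n, 0);
  }

  static int64_t ekey(int a, int b) {
    if (a > b) std::swap(a, b);
    return (int64_t)a * 1000000007LL + b;
  }

  bool dir_free(int from, int to) const {
    auto it = edges.find(ekey(from, to));
    if (it == edges.end()) return true;
    if (it->second.count >= 2) return false;
    int bit = from < to ? 1 : 2;
    return (it->second.dir_used & bit) == 0;
  }

  V3 tri_normal(int t) const {
    const auto& f = tris[t];
    return (P[f[1]] - P[f[0]]).cross(P[f[2]] - P[f[0]]);
  }

  bool edge_exists(int a, int b) const {
    auto it = edges.find(ekey(a, b));
    return it != edges.end() && it->second.count > 0;
  }

  // does the oriented triangle (v0,v1,v2) fit the current front?
  // apex >= 0 marks the candidate's apex vertex: if it is already part of
  // the mesh it must extend an existing fan (share an edge with the front
  // edge), which prevents crossing-sheet triangle soup at open vertices
  bool tri_valid(int v0, int v1, int v2, int apex = -1) const {
    if (v0 == v1 || v1 == v2 || v0 == v2) return false;
    if (apex >= 0 && used[apex]) {
      int o1 = apex == v2 ? v0 : (apex == v0 ? v1 : v0);
      int o2 = apex == v2 ? v1 : (apex == v0 ? v2 : v2);
      if (!edge_exists(apex, o1) && !edge_exists(apex, o2)) return false;
    }
    int vs[3] = {v0, v1, v2};
    for (int e = 0; e < 3; ++e) {
      int a = vs[e], b = vs[(e + 1) % 3];
      if (!dir_free(a, b)) return false;
    }
    // orientation compatibility with existing neighbors across each edge
    V3 nrm = (P[v1] - P[v0]).cross(P[v2] - P[v0]);
    double nn = nrm.norm();
    if (nn < 1e-300) return false;
    for (int e = 0; e < 3; ++e) {
      int a = vs[e], b = vs[(e + 1) % 3];
      auto it = edges.find(ekey(a, b));
      if (it == edges.end() || it->second.count == 0) continue;
      V3 on = tri_normal(it->second.tri[0]);
      double od = on.norm();
      if (od < 1e-300) continue;
      if (nrm.dot(on) / (nn * od) < min_dot) return false;
    }
    return true;
  }

  void add_tri(int v0, int v1, int v2) {
    int t = (int)tris.size();
    tris.push_back({v0, v1, v2});
    used[v0] = used[v1] = used[v2] = 1;
    int vs[3] = {v0, v1, v2};
    for (int e = 0; e < 3; ++e) {
      int a = vs[e], b = vs[(e + 1) % 3];
      EdgeInfo& ei = edges[ekey(a, b)];
      ei.tri[ei.count < 2 ? ei.count : 1] = t;
      ei.count++;
      ei.dir_used |= (a < b ? 1 : 2);
    }
    // push candidates across each still-open edge
    for (int e = 0; e < 3; ++e) {
      int a = vs[e], b = vs[(e + 1) % 3];
      if (edges[ekey(a, b)].count == 1) push_candidates(b, a);  // free direction
    }
  }

  // candidates for the open directed edge from->to
  void push_candidates(int from, int to) {
    std::unordered_set<int> cs;
    for (int c : nb[from]) cs.insert(c);
    for (int c : nb[to]) cs.insert(c);
    for (int c : cs) {
      if (c == from || c == to) continue;
      double r = circumradius(P[from], P[to], P[c]);
      if (r > rmax) continue;
      if (!tri_valid(from, to, c, c)) continue;
      queue.push({r, from, to, c});
    }
  }

  bool seed(bool only_unused) {
    Cand best{1e300, -1, -1, -1};
    for (int i = 0; i < n; ++i) {
      if (only_unused && used[i]) continue;
      const auto& ni = nb[i];
      for (size_t a = 0; a < ni.size(); ++a) {
        if (only_unused && used[ni[a]]) continue;
        for (size_t b = a + 1; b < ni.size(); ++b) {
          if (only_unused && used[ni[b]]) continue;
          double r = circumradius(P[i], P[ni[a]], P[ni[b]]);
          if (r < best.r) best = {r, i, ni[a], ni[b]};
        }
      }
    }
    if (best.v0 < 0 || best.r > rmax) return false;
    if (!tri_valid(best.v0, best.v1, best.v2)) return false;
    add_tri(best.v0, best.v1, best.v2);
    return true;
  }

  void grow() {
    while (true) {
      bool advanced = false;
      while (!queue.empty()) {
        Cand c = queue.top();
        queue.pop();
        // revalidate lazily: the edge must still be open in that direction
        if (!dir_free(c.v0, c.v1)) continue;
        auto it = edges.find(ekey(c.v0, c.v1));
        if (it == edges.end() || it->second.count != 1) continue;
        if (!tri_valid(c.v0, c.v1, c.v2, c.v2)) continue;
        add_tri(c.v0, c.v1, c.v2);
        advanced = true;
      }
      // discontinuity: reseed among unused points
      if (!seed(true)) break;
      if (!advanced && queue.empty()) break;
    }
  }

  // close boundary cycles with at most max_hole edges by ear filling
  void fill_holes(int max_hole) {
    // free directed edges: reverse of the used direction on count-1 edges
    std::unordered_map<int, std::vector<int>> out;  // vertex -> free targets
    for (auto& kv : edges) {
      if (kv.second.count != 1) continue;
      int64_t k = kv.first;
      int a = (int)(k / 1000000007LL), b = (int)(k % 1000000007LL);
      // used direction bit
      if (kv.second.dir_used & 1) out[b].push_back(a);  // lo->hi used, free hi->lo
      else out[a].push_back(b);
    }
    std::unordered_set<int64_t> visited;
    std::vector<std::vector<int>> cycles;
    for (auto& kv : out) {
      for (int tgt : kv.second) {
        int64_t ek0 = ekey(kv.first, tgt);
        if (visited.count(ek0)) continue;
        // trace cycle
        std::vector<int> cyc;
        int cur = kv.first, nxt = tgt;
        bool closed = false;
        for (int steps = 0; steps <= max_hole + 1; ++steps) {
          cyc.push_back(cur);
          auto oi = out.find(cur);
          if (oi == out.end()) break;
          // pick the free edge continuing to nxt
          bool found = false;
          for (int t2 : oi->second)
            if (t2 == nxt) { found = true; break; }
          if (!found) break;
          if (nxt == kv.first) { closed = true; break; }
          cur = nxt;
          auto oj = out.find(cur);
          if (oj == out.end() || oj->second.empty()) break;
          nxt = oj->second[0];  // boundary vertices normally have one exit
        }
        if (closed && (int)cyc.size() >= 3 && (int)cyc.size() <= max_hole) {
          for (size_t i2 = 0; i2 < cyc.size(); ++i2)
            visited.insert(ekey(cyc[i2], cyc[(i2 + 1) % cyc.size()]));
          cycles.push_back(cyc);
        } else {
          visited.insert(ek0);
        }
      }
    }
    for (auto& cyc : cycles) {
      std::vector<int> c = cyc;
      while ((int)c.size() > 3) {
        // clip the ear with the smallest circumradius
        int best = -1;
        double bestr = 1e300;
        int m = (int)c.size();
        for (int i = 0; i < m; ++i) {
          int u = c[i], v = c[(i + 1) % m], w = c[(i + 2) % m];
          if (!tri_valid(u, v, w)) continue;
          double r = circumradius(P[u], P[v], P[w]);
          if (r < bestr) { bestr = r; best = i; }
        }
        if (best < 0) break;
        int u = c[best], v = c[(best + 1) % m], w = c[(best + 2) % m];
        add_tri(u, v, w);
        c.erase(c.begin() + (best + 1) % m);
      }
      if ((int)c.size() == 3 && tri_valid(c[0], c[1], c[2]))
        add_tri(c[0], c[1], c[2]);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_advancing_front(NumericMatrix P, List knn, double rmax,
                                  double min_dot, int max_hole) {
  int n = P.nrow();
  std::vector<V3> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = knn[i];
    nb[i].reserve(v.size());
    for (int j = 0; j < v.size(); ++j)
      if (v[j] != NA_INTEGER) nb[i].push_back(v[j] - 1);
  }
  Front fr(pts, nb, rmax, min_dot);
  if (!fr.seed(false)) return IntegerMatrix(0, 3);
  fr.grow();
  if (max_hole >= 3) {
    fr.fill_holes(max_hole);
    // hole filling can reopen the front where new edges enable candidates
    fr.grow();
  }
  int m = (int)fr.tris.size();
  IntegerMatrix out(m, 3);
  for (int t = 0; t < m; ++t)
    for (int e = 0; e < 3; ++e) out(t, e) = fr.tris[t][e] + 1;
  return out;
}
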