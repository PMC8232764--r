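// 3-d kd-tree used by neighborhood queries throughout the package.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
#include <array>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct KDTree {
  std::vector<std::array<double, 3>> pts;
  std::vector<int> perm;        // point indices in tree order
  std::vector<int> split_axis;  // per tree node (implicit balanced layout)

  explicit KDTree(const NumericMatrix& P) {
    int n = P.nrow();
    pts.resize(n);
    for (int i = 0; i < n; ++i) pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    split_axis.assign(n, 0);
    build(0, n);
  }

  // recursive median build over perm[lo, hi)
  void build(int lo, int hi) {
    if (hi - lo <= 1) return;
    double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double v = pts[perm[i]][a];
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int ax = 0;
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > mx[ax] - mn[ax]) ax = a;
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int i, int j) { return pts[i][ax] < pts[j][ax]; });
    split_axis[mid] = ax;
    build(lo, mid);
    build(mid + 1, hi);
  }

  static double d2(const std::array<double, 3>& a, const std::array<double, 3>& b) {
    double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
    return dx * dx + dy * dy + dz * dz;
  }

  // k nearest neighbors of q; `skip` (>= 0) excludes one point index (self).
  void knn(const std::array<double, 3>& q, int k, int skip,
           std::vector<int>& out_idx, std::vector<double>& out_d2) const {
    // max-heap of (dist2, idx)
    std::priority_queue<std::pair<double, int>> heap;
    knn_rec(0, (int)pts.size(), q, k, skip, heap);
    int m = (int)heap.size();
    out_idx.assign(m, -1);
    out_d2.assign(m, 0.0);
    for (int i = m - 1; i >= 0; --i) {
      out_idx[i] = heap.top().second;
      out_d2[i] = heap.top().first;
      heap.pop();
    }
  }

  void knn_rec(int lo, int hi, const std::array<double, 3>& q, int k, int skip,
               std::priority_queue<std::pair<double, int>>& heap) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int pi = perm[mid];
    if (pi != skip) {
      double dd = d2(q, pts[pi]);
      if ((int)heap.size() < k) heap.push({dd, pi});
      else if (dd < heap.top().first ||
               (dd == heap.top().first && pi < heap.top().second)) {
        heap.pop();
        heap.push({dd, pi});
      }
    }
    if (hi - lo == 1) return;
    int ax = split_axis[mid];
    double diff = q[ax] - pts[pi][ax];
    int nlo1 = lo, nhi1 = mid, nlo2 = mid + 1, nhi2 = hi;
    if (diff > 0) { std::swap(nlo1, nlo2); std::swap(nhi1, nhi2); }
    knn_rec(nlo1, nhi1, q, k, skip, heap);
    if ((int)heap.size() < k || diff * diff <= heap.top().first)
      knn_rec(nlo2, nhi2, q, k, skip, heap);
  }

  void radius(const std::array<double, 3>& q, double r2, int skip,
              std::vector<int>& out) const {
    radius_rec(0, (int)pts.size(), q, r2, skip, out);
  }

  void radius_rec(int lo, int hi, const std::array<double, 3>& q, double r2,
                  int skip, std::vector<int>& out) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int pi = perm[mid];
    if (pi != skip && d2(q, pts[pi]) <= r2) out.push_back(pi);
    if (hi - lo == 1) return;
    int ax = split_axis[mid];
    double diff = q[ax] - pts[pi][ax];
    if (diff <= 0) {
      radius_rec(lo, mid, q, r2, skip, out);
      if (diff * diff <= r2) radius_rec(mid + 1, hi, q, r2, skip, out);
    } else {
      radius_rec(mid + 1, hi, q, r2, skip, out);
      if (diff * diff <= r2) radius_rec(lo, mid, q, r2, skip, out);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_knn(NumericMatrix pts, NumericMatrix queries, int k, bool self) {
  KDTree tree(pts);
  int nq = queries.nrow();
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<int> oi;
  std::vector<double> od;
  for (int i = 0; i < nq; ++i) {
    std::array<double, 3> q = {queries(i, 0), queries(i, 1), queries(i, 2)};
    tree.knn(q, k, self ? i : -1, oi, od);
    int m = (int)oi.size();
    for (int j = 0; j < k; ++j) {
      idx(i, j) = j < m ? oi[j] + 1 : NA_INTEGER;
      dist(i, j) = j < m ? std::sqrt(od[j]) : NA_REAL;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// [[Rcpp::export]]
List cpp_radius_search(NumericMatrix pts, NumericMatrix queries, double r, bool self) {
  KDTree tree(pts);
  int nq = queries.nrow();
  List out(nq);
  std::vector<int> oi;
  for (int i = 0; i < nq; ++i) {
    oi.clear();
    std::array<double, 3> q = {queries(i, 0), queries(i, 1), queries(i, 2)};
    tree.radius(q, r * r, self ? i : -1, oi);
    std::sort(oi.begin(), oi.end());
    IntegerVector v(oi.size());
    for (size_t j = 0; j < oi.size(); ++j) v[j] = oi[j] + 1;
    out[i] = v;
  }
  return out;
}

// PCA normals: smallest-eigenvalue eigenvector of the k-neighborhood
// covariance, oriented toward `viewpoint`. A neighborhood whose two smallest
// eigenvalues both vanish (collinear points) yields an invalid normal.
// [[Rcpp::export]]
List cpp_pca_normals(NumericMatrix pts, int k, NumericVector viewpoint) {
  KDTree tree(pts);
  int n = pts.nrow();
  NumericMatrix normals(n, 3);
  LogicalVector valid(n);
  std::vector<int> oi;
  std::vector<double> od;
  arma::mat33 C;
  arma::vec3 eval;
  arma::mat33 evec;
  for (int i = 0; i < n; ++i) {
    std::array<double, 3> q = {pts(i, 0), pts(i, 1), pts(i, 2)};
    tree.knn(q, k, i, oi, od);
    int m = (int)oi.size();
    double mx = 0, my = 0, mz = 0;
    for (int j = 0; j < m; ++j) {
      mx += pts(oi[j], 0); my += pts(oi[j], 1); mz += pts(oi[j], 2);
    }
    mx += q[0]; my += q[1]; mz += q[2];
    double inv = 1.0 / (m + 1);
    mx *= inv; my *= inv; mz *= inv;
    C.zeros();
    for (int j = 0; j <= m; ++j) {
      double dx, dy, dz;
      if (j < m) { dx = pts(oi[j], 0) - mx; dy = pts(oi[j], 1) - my; dz = pts(oi[j], 2) - mz; }
      else { dx = q[0] - mx; dy = q[1] - my; dz = q[2] - mz; }
      C(0, 0) += dx * dx; C(0, 1) += dx * dy; C(0, 2) += dx * dz;
      C(1, 1) += dy * dy; C(1, 2) += dy * dz; C(2, 2) += dz * dz;
    }
    C(1, 0) = C(0, 1); C(2, 0) = C(0, 2); C(2, 1) = C(1, 2);
    arma::eig_sym(eval, evec, C);
    // eval ascending; collinear neighborhood: two smallest eigenvalues ~ 0
    double scale = eval(2);
    bool ok = m >= 2 && scale > 0 && eval(1) > 1e-9 * scale;
    valid[i] = ok;
    if (ok) {
      double nx = evec(0, 0), ny = evec(1, 0), nz = evec(2, 0);
      double dot = nx * (viewpoint[0] - q[0]) + ny * (viewpoint[1] - q[1]) +
                   nz * (viewpoint[2] - q[2]);
      if (dot < 0) { nx = -nx; ny = -ny; nz = -nz; }
      normals(i, 0) = nx; normals(i, 1) = ny; normals(i, 2) = nz;
    } else {
      normals(i, 0) = NA_REAL; normals(i, 1) = NA_REAL; normals(i, 2) = NA_REAL;
    }
  }
  return List::create(_["normals"] = normals, _["valid"] = valid);
}
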