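// Triangle-mesh distance queries, mesh -> sparse TSDF conversion, and a
// z-buffer depth rasterizer for the synthetic scene generator.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct P3 {
  double x, y, z;
  P3 operator-(const P3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  P3 operator+(const P3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  P3 operator*(double s) const { return {x * s, y * s, z * s}; }
  double dot(const P3& o) const { return x * o.x + y * o.y + z * o.z; }
  P3 cross(const P3& o) const {
    return {y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x};
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
P3 closest_on_tri(const P3& p, const P3& a, const P3& b, const P3& c) {
  P3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0 && d2 <= 0) return a;
  P3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  P3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && d4 - d3 >= 0 && d5 - d6 >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

inline int64_t vkey(int i, int j, int k) {
  const int64_t M = 1 << 20;
  return (((int64_t)(i + M)) << 42) | (((int64_t)(j + M)) << 21) | (int64_t)(k + M);
}

}  // namespace

// distance from point p to segment [a, b]
static double seg_dist(const P3& p, const P3& a, const P3& b) {
  P3 ab = b - a;
  double t = ab.dot(p - a) / std::max(ab.dot(ab), 1e-300);
  t = std::max(0.0, std::min(1.0, t));
  P3 q = a + ab * t;
  return (p - q).norm();
}

// Convert a triangle mesh to a sparse truncated signed-distance volume.
// sign_mode 0: orient each triangle toward `viewpoint` (single-view capture);
// sign_mode 1: trust the mesh winding (closed synthetic meshes, outward +).
// Voxels whose closest feature is a mesh-boundary edge and whose centre lies
// laterally beyond the sheet rim (by more than rim_band metres) have no
// well-defined crossing; their weight is scaled by rim_weight (0 drops them
// from polygonization via the weight-positive extraction rule).
// [[Rcpp::export]]
List cpp_mesh_tsdf(NumericMatrix V, IntegerMatrix F, double voxel, double trunc,
                   NumericVector origin, int sign_mode, NumericVector viewpoint,
                   IntegerMatrix bnd_edge, double rim_band, double rim_weight) {
  int nf = F.nrow();
  struct Rec {
    double adist;   // |distance|
    double sval;    // signed distance
    double align;   // |cos| between (c - closest) and triangle normal
    double wfac;    // rim damping factor of the winning triangle
  };
  std::unordered_map<int64_t, Rec> best;
  for (int t = 0; t < nf; ++t) {
    P3 a = {V(F(t, 0) - 1, 0), V(F(t, 0) - 1, 1), V(F(t, 0) - 1, 2)};
    P3 b = {V(F(t, 1) - 1, 0), V(F(t, 1) - 1, 1), V(F(t, 1) - 1, 2)};
    P3 c = {V(F(t, 2) - 1, 0), V(F(t, 2) - 1, 1), V(F(t, 2) - 1, 2)};
    P3 nrm = (b - a).cross(c - a);
    double nn = nrm.norm();
    if (nn < 1e-300) continue;
    nrm = nrm * (1.0 / nn);
    bool has_bnd = bnd_edge(t, 0) || bnd_edge(t, 1) || bnd_edge(t, 2);
    if (sign_mode == 0) {
      P3 cen = (a + b + c) * (1.0 / 3.0);
      P3 tov = {viewpoint[0] - cen.x, viewpoint[1] - cen.y, viewpoint[2] - cen.z};
      if (nrm.dot(tov) < 0) nrm = nrm * -1.0;
    }
    double lox = std::min({a.x, b.x, c.x}) - trunc, hix = std::max({a.x, b.x, c.x}) + trunc;
    double loy = std::min({a.y, b.y, c.y}) - trunc, hiy = std::max({a.y, b.y, c.y}) + trunc;
    double loz = std::min({a.z, b.z, c.z}) - trunc, hiz = std::max({a.z, b.z, c.z}) + trunc;
    // voxel centre of index i is origin + (i + 0.5) * voxel
    int i0 = (int)std::floor((lox - origin[0]) / voxel - 0.5);
    int i1 = (int)std::ceil((hix - origin[0]) / voxel - 0.5);
    int j0 = (int)std::floor((loy - origin[1]) / voxel - 0.5);
    int j1 = (int)std::ceil((hiy - origin[1]) / voxel - 0.5);
    int k0 = (int)std::floor((loz - origin[2]) / voxel - 0.5);
    int k1 = (int)std::ceil((hiz - origin[2]) / voxel - 0.5);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k) {
          P3 cc = {origin[0] + (i + 0.5) * voxel,
                   origin[1] + (j + 0.5) * voxel,
                   origin[2] + (k + 0.5) * voxel};
          P3 cp = closest_on_tri(cc, a, b, c);
          P3 dvec = cc - cp;
          double d = dvec.norm();
          if (d > trunc) continue;
          double sd = nrm.dot(dvec);
          double sgn = sd >= 0 ? 1.0 : -1.0;
          double align = d > 1e-300 ? std::fabs(sd) / d : 1.0;
          double wfac = 1.0;
          if (has_bnd) {
            // closest feature on a boundary edge + lateral offset beyond it?
            const P3* vs3[3] = {&a, &b, &c};
            bool on_bnd = false;
            for (int e = 0; e < 3; ++e) {
              if (!bnd_edge(t, e)) continue;
              if (seg_dist(cp, *vs3[e], *vs3[(e + 1) % 3]) < 1e-9) {
                on_bnd = true;
                break;
              }
            }
            if (on_bnd) {
              P3 lat = dvec - nrm * sd;
              if (lat.norm() > rim_band) wfac = rim_weight;
            }
          }
          int64_t kk = vkey(i, j, k);
          auto it = best.find(kk);
          // keep the closest triangle; among near-ties prefer the one whose
          // normal is better aligned with the offset (pseudo-normal rule)
          if (it == best.end() || d < it->second.adist - 1e-12 ||
              (d < it->second.adist + 1e-12 && align > it->second.align)) {
            best[kk] = {d, sgn * d, align, wfac};
          }
        }
  }
  int n = (int)best.size();
  IntegerMatrix ijk(n, 3);
  NumericVector val(n), wt(n);
  int r = 0;
  const int64_t M = 1 << 20;
  for (auto& kv : best) {
    int64_t k = kv.first;
    ijk(r, 0) = (int)((k >> 42) & 0x1FFFFF) - (int)M;
    ijk(r, 1) = (int)((k >> 21) & 0x1FFFFF) - (int)M;
    ijk(r, 2) = (int)(k & 0x1FFFFF) - (int)M;
    double v = kv.second.sval / trunc;
    val[r] = std::max(-1.0, std::min(1.0, v));
    wt[r] = (1.0 - kv.second.adist / trunc) * kv.second.wfac;
    ++r;
  }
  return List::create(_["ijk"] = ijk, _["value"] = val, _["weight"] = wt);
}

// Closest point on a mesh for each query point, accelerated by a uniform
// grid over triangle bounding boxes.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow(), np = P.nrow();
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < V.nrow(); ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], V(i, a));
      hi[a] = std::max(hi[a], V(i, a));
    }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  // cell size ~ mean triangle extent, bounded below
  double mext = 0;
  for (int t = 0; t < nf; ++t) {
    double ext = 0;
    for (int a = 0; a < 3; ++a) {
      double l = std::min({V(F(t, 0) - 1, a), V(F(t, 1) - 1, a), V(F(t, 2) - 1, a)});
      double h = std::max({V(F(t, 0) - 1, a), V(F(t, 1) - 1, a), V(F(t, 2) - 1, a)});
      ext = std::max(ext, h - l);
    }
    mext += ext;
  }
  double cell = std::max(nf > 0 ? 1.5 * mext / nf : diag, diag / 128 + 1e-12);
  std::unordered_map<int64_t, std::vector<int>> grid;
  auto cidx = [&](double x, int a) { return (int)std::floor((x - lo[a]) / cell); };
  for (int t = 0; t < nf; ++t) {
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      double l = std::min({V(F(t, 0) - 1, a), V(F(t, 1) - 1, a), V(F(t, 2) - 1, a)});
      double h = std::max({V(F(t, 0) - 1, a), V(F(t, 1) - 1, a), V(F(t, 2) - 1, a)});
      c0[a] = cidx(l, a);
      c1[a] = cidx(h, a);
    }
    for (int i = c0[0]; i <= c1[0]; ++i)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int k = c0[2]; k <= c1[2]; ++k) grid[vkey(i, j, k)].push_back(t);
  }
  NumericMatrix CP(np, 3);
  NumericVector D(np);
  IntegerVector TRI(np);
  for (int q = 0; q < np; ++q) {
    P3 p = {P(q, 0), P(q, 1), P(q, 2)};
    int ci = cidx(p.x, 0), cj = cidx(p.y, 1), ck = cidx(p.z, 2);
    double bd = 1e300;
    P3 bp = p;
    int bt = -1;
    for (int ring = 0;; ++ring) {
      // once a hit exists, stop when the next ring cannot improve
      if (bt >= 0 && (double)(ring - 1) * cell > bd) break;
      bool any_cell = false;
      for (int i = ci - ring; i <= ci + ring; ++i)
        for (int j = cj - ring; j <= cj + ring; ++j)
          for (int k = ck - ring; k <= ck + ring; ++k) {
            if (std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)}) != ring)
              continue;
            auto it = grid.find(vkey(i, j, k));
            if (it == grid.end()) continue;
            any_cell = true;
            for (int t : it->second) {
              P3 a = {V(F(t, 0) - 1, 0), V(F(t, 0) - 1, 1), V(F(t, 0) - 1, 2)};
              P3 b = {V(F(t, 1) - 1, 0), V(F(t, 1) - 1, 1), V(F(t, 1) - 1, 2)};
              P3 c = {V(F(t, 2) - 1, 0), V(F(t, 2) - 1, 1), V(F(t, 2) - 1, 2)};
              P3 cp = closest_on_tri(p, a, b, c);
              double d = (p - cp).norm();
              if (d < bd) { bd = d; bp = cp; bt = t; }
            }
          }
      (void)any_cell;
      if (ring > 2 * (int)(diag / cell) + 2) break;  // safety
    }
    CP(q, 0) = bp.x; CP(q, 1) = bp.y; CP(q, 2) = bp.z;
    D[q] = bd;
    TRI[q] = bt + 1;
  }
  return List::create(_["points"] = CP, _["dist"] = D, _["tri"] = TRI);
}

// Perspective z-buffer rasterization of a triangle mesh already expressed in
// camera coordinates (x right, y down, z forward). Returns an h x w matrix of
// metric depths, 0 where nothing was hit.
// [[Rcpp::export]]
NumericMatrix cpp_rasterize(NumericMatrix V, IntegerMatrix F, int width, int height,
                            double fx, double fy, double cx, double cy) {
  NumericMatrix Z(height, width);  // 0 = empty
  int nf = F.nrow();
  const double znear = 1e-4;
  for (int t = 0; t < nf; ++t) {
    double x[3], y[3], z[3], u[3], v[3];
    bool ok = true;
    for (int s = 0; s < 3; ++s) {
      int vi = F(t, s) - 1;
      x[s] = V(vi, 0); y[s] = V(vi, 1); z[s] = V(vi, 2);
      if (z[s] <= znear) { ok = false; break; }
      u[s] = x[s] / z[s] * fx + cx;
      v[s] = y[s] / z[s] * fy + cy;
    }
    if (!ok) continue;
    int u0 = std::max(0, (int)std::floor(std::min({u[0], u[1], u[2]})));
    int u1 = std::min(width - 1, (int)std::ceil(std::max({u[0], u[1], u[2]})));
    int v0 = std::max(0, (int)std::floor(std::min({v[0], v[1], v[2]})));
    int v1 = std::min(height - 1, (int)std::ceil(std::max({v[0], v[1], v[2]})));
    if (u0 > u1 || v0 > v1) continue;
    double det = (u[1] - u[0]) * (v[2] - v[0]) - (u[2] - u[0]) * (v[1] - v[0]);
    if (std::fabs(det) < 1e-12) continue;
    for (int pv = v0; pv <= v1; ++pv)
      for (int pu = u0; pu <= u1; ++pu) {
        double pux = pu, pvy = pv;  // sample at integer pixel coordinate
        double w1 = ((pux - u[0]) * (v[2] - v[0]) - (u[2] - u[0]) * (pvy - v[0])) / det;
        double w2 = ((u[1] - u[0]) * (pvy - v[0]) - (pux - u[0]) * (v[1] - v[0])) / det;
        double w0 = 1.0 - w1 - w2;
        const double eps = -1e-9;
        if (w0 < eps || w1 < eps || w2 < eps) continue;
        // perspective-correct depth: interpolate 1/z in screen space
        double invz = w0 / z[0] + w1 / z[1] + w2 / z[2];
        if (invz <= 0) continue;
        double depth = 1.0 / invz;
        double cur = Z(pv, pu);
        if (cur == 0 || depth < cur) Z(pv, pu) = depth;
      }
  }
  return Z;
}

// CRC-32 (PNG/zlib polynomial) of a raw vector, with an optional running
// value so chunk type + data can be combined.
// [[Rcpp::export]]
double cpp_crc32(RawVector data, double init) {
  static uint32_t table[256];
  static bool have = false;
  if (!have) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have = true;
  }
  uint32_t crc = ~(uint32_t)init;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFF] ^ (crc >> 8);
  return (double)(~crc);
}
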