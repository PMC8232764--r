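// Marching cubes over a sparse TSDF voxel map.
//
// Cubes are formed by 8 adjacent voxel centres; only cubes whose corners are
// all materialized with positive weight are polygonized. Instead of the
// classic 256-entry lookup table, each cube's zero-isoline polygons are built
// constructively: cut edges are paired per face (ambiguous faces resolved by
// always separating the negative corners, a rule that depends only on the
// face and is therefore crack-free across neighboring cubes) and walked into
// closed polygons, then fan-triangulated. Crossing positions use linear
// interpolation along cube edges; shared vertices are welded via a global
// lattice-edge key.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// corner c in 0..7 has offsets (bit0, bit1, bit2) along x, y, z
const int FACES[6][4] = {
    {0, 2, 6, 4},  // x = 0
    {1, 3, 7, 5},  // x = 1
    {0, 1, 5, 4},  // y = 0
    {2, 3, 7, 6},  // y = 1
    {0, 1, 3, 2},  // z = 0
    {4, 5, 7, 6}   // z = 1
};

inline int64_t vkey(int i, int j, int k) {
  const int64_t M = 1 << 20;
  return (((int64_t)(i + M)) << 42) | (((int64_t)(j + M)) << 21) | (int64_t)(k + M);
}

struct EdgeRef {
  int a, b;  // local corners
};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_cubes(IntegerMatrix ijk, NumericVector val, NumericVector wt,
                        double voxel, NumericVector origin) {
  int n = ijk.nrow();
  std::unordered_map<int64_t, int> vox;
  vox.reserve(n * 2);
  for (int i = 0; i < n; ++i) vox[vkey(ijk(i, 0), ijk(i, 1), ijk(i, 2))] = i;

  // 12 cube edges as corner pairs, and the two faces adjacent to each edge
  EdgeRef edges[12];
  int ne = 0;
  int edge_id[8][8];
  for (int a = 0; a < 8; ++a)
    for (int b = 0; b < 8; ++b) edge_id[a][b] = -1;
  for (int a = 0; a < 8; ++a)
    for (int b = a + 1; b < 8; ++b) {
      int d = a ^ b;
      if (d == 1 || d == 2 || d == 4) {
        edges[ne] = {a, b};
        edge_id[a][b] = edge_id[b][a] = ne;
        ++ne;
      }
    }
  int edge_faces[12][2];
  for (int e = 0; e < 12; ++e) edge_faces[e][0] = edge_faces[e][1] = -1;
  for (int f = 0; f < 6; ++f)
    for (int s = 0; s < 4; ++s) {
      int a = FACES[f][s], b = FACES[f][(s + 1) % 4];
      int e = edge_id[a][b];
      if (edge_faces[e][0] < 0) edge_faces[e][0] = f;
      else edge_faces[e][1] = f;
    }

  std::vector<double> V;     // welded vertex coordinates
  std::vector<int> F;        // triangles (0-based)
  std::unordered_map<int64_t, int> vcache;  // lattice edge -> vertex id

  for (int c0 = 0; c0 < n; ++c0) {
    int ci = ijk(c0, 0), cj = ijk(c0, 1), ck = ijk(c0, 2);
    int corner_idx[8];
    bool all = true;
    for (int c = 0; c < 8; ++c) {
      auto it = vox.find(vkey(ci + (c & 1), cj + ((c >> 1) & 1), ck + ((c >> 2) & 1)));
      if (it == vox.end() || wt[it->second] <= 0) { all = false; break; }
      corner_idx[c] = it->second;
    }
    if (!all) continue;
    bool inside[8];
    int nin = 0;
    double cv[8];
    for (int c = 0; c < 8; ++c) {
      cv[c] = val[corner_idx[c]];
      inside[c] = cv[c] < 0;
      if (inside[c]) ++nin;
    }
    if (nin == 0 || nin == 8) continue;

    bool cut[12];
    for (int e = 0; e < 12; ++e) cut[e] = inside[edges[e].a] != inside[edges[e].b];

    // pair cut edges per face
    int partner[12][6];
    for (int e = 0; e < 12; ++e)
      for (int f = 0; f < 6; ++f) partner[e][f] = -1;
    for (int f = 0; f < 6; ++f) {
      int ce[4], nc = 0;
      for (int s = 0; s < 4; ++s) {
        int e = edge_id[FACES[f][s]][FACES[f][(s + 1) % 4]];
        if (cut[e]) ce[nc++] = s;
      }
      if (nc == 2) {
        int e1 = edge_id[FACES[f][ce[0]]][FACES[f][(ce[0] + 1) % 4]];
        int e2 = edge_id[FACES[f][ce[1]]][FACES[f][(ce[1] + 1) % 4]];
        partner[e1][f] = e2;
        partner[e2][f] = e1;
      } else if (nc == 4) {
        // ambiguous face: separate the negative corners
        for (int s = 0; s < 4; ++s) {
          if (!inside[FACES[f][s]]) continue;
          int ep = edge_id[FACES[f][(s + 3) % 4]][FACES[f][s]];
          int en = edge_id[FACES[f][s]][FACES[f][(s + 1) % 4]];
          partner[ep][f] = en;
          partner[en][f] = ep;
        }
      }
    }

    // walk polygons
    bool done[12] = {false};
    for (int e0 = 0; e0 < 12; ++e0) {
      if (!cut[e0] || done[e0]) continue;
      std::vector<int> poly;
      int e = e0, f = edge_faces[e0][0];
      // arrive at each edge via face f, leave via the other face
      while (true) {
        poly.push_back(e);
        done[e] = true;
        int g = edge_faces[e][0] == f ? edge_faces[e][1] : edge_faces[e][0];
        int nxt = partner[e][g];
        f = g;
        e = nxt;
        if (e == e0) break;
      }
      if (poly.size() < 3) continue;

      // vertex position and global weld key per polygon edge
      std::vector<int> vid(poly.size());
      std::vector<double> px(poly.size()), py(poly.size()), pz(poly.size());
      for (size_t q = 0; q < poly.size(); ++q) {
        int a = edges[poly[q]].a, b = edges[poly[q]].b;
        double va = cv[a], vb = cv[b];
        double t = va / (va - vb);
        if (!std::isfinite(t)) t = 0.5;
        double ax = ci + (a & 1), ay = cj + ((a >> 1) & 1), az = ck + ((a >> 2) & 1);
        double bx = ci + (b & 1), by = cj + ((b >> 1) & 1), bz = ck + ((b >> 2) & 1);
        px[q] = origin[0] + (ax + 0.5 + t * (bx - ax)) * voxel;
        py[q] = origin[1] + (ay + 0.5 + t * (by - ay)) * voxel;
        pz[q] = origin[2] + (az + 0.5 + t * (bz - az)) * voxel;
        // weld key: lattice point of lower corner + axis (2 bits)
        int axbit = (a ^ b) == 1 ? 0 : ((a ^ b) == 2 ? 1 : 2);
        int lo = (a & (a ^ b)) ? b : a;
        int64_t kk = vkey(ci + (lo & 1), cj + ((lo >> 1) & 1), ck + ((lo >> 2) & 1));
        int64_t wk = kk * 4 + axbit;
        auto it = vcache.find(wk);
        if (it == vcache.end()) {
          int id = (int)(V.size() / 3);
          V.push_back(px[q]); V.push_back(py[q]); V.push_back(pz[q]);
          vcache[wk] = id;
          vid[q] = id;
        } else {
          vid[q] = it->second;
        }
      }

      // orient: normal should point from inside (negative) to outside
      double nx = 0, ny = 0, nz = 0;  // Newell
      int m = (int)poly.size();
      for (int q = 0; q < m; ++q) {
        int r = (q + 1) % m;
        nx += (py[q] - py[r]) * (pz[q] + pz[r]);
        ny += (pz[q] - pz[r]) * (px[q] + px[r]);
        nz += (px[q] - px[r]) * (py[q] + py[r]);
      }
      double dx = 0, dy = 0, dz = 0;
      for (int q = 0; q < m; ++q) {
        int a = edges[poly[q]].a, b = edges[poly[q]].b;
        int in = inside[a] ? a : b, out = inside[a] ? b : a;
        dx += ((out & 1) - (in & 1));
        dy += (((out >> 1) & 1) - ((in >> 1) & 1));
        dz += (((out >> 2) & 1) - ((in >> 2) & 1));
      }
      bool flip = nx * dx + ny * dy + nz * dz < 0;
      for (int q = 1; q + 1 < m; ++q) {
        if (flip) {
          F.push_back(vid[0]); F.push_back(vid[q + 1]); F.push_back(vid[q]);
        } else {
          F.push_back(vid[0]); F.push_back(vid[q]); F.push_back(vid[q + 1]);
        }
      }
    }
  }

  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vm(i, 0) = V[3 * i]; Vm(i, 1) = V[3 * i + 1]; Vm(i, 2) = V[3 * i + 2];
  }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = F[3 * i] + 1; Fm(i, 1) = F[3 * i + 1] + 1; Fm(i, 2) = F[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["triangles"] = Fm);
}
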