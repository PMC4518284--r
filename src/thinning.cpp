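#include <Rcpp.h>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

// Topology-preserving 3D thinning for the (26, 6) digital topology pair
// (26-connected foreground, 6-connected background).
//
// A border voxel is deleted only while it is a *simple point* in the sense of
// Bertrand & Malandain: deleting it changes neither the number of 26-connected
// foreground components nor the number of 6-connected background components
// locally. The characterization used:
//   (a) the foreground voxels of the 26-neighborhood form exactly one
//       26-connected component, and
//   (b) the background voxels of the 18-neighborhood that are 6-adjacent to
//       the center form exactly one 6-connected component within N18.
// Deletion is sequential inside each directional subiteration (each candidate
// is re-checked at deletion time), which guarantees topology preservation.
// Curve endpoints (exactly one foreground 26-neighbor) are never deleted, so
// tubes thin to centerlines instead of shrinking to points.
//
// Subiteration order is fixed (N, S, E, W, U, D) = (-y, +y, +x, -x, +z, -z)
// for deterministic output; eroding the transverse directions before the
// longitudinal ones keeps the medial axis of axis-aligned tubes centered.

namespace {

struct Neigh {
  int off[27][3];          // offset vectors, index = (dz+1)*9+(dy+1)*3+(dx+1)
  bool adj26[27][27];      // 26-adjacency between neighborhood cells
  bool adj6[27][27];       // 6-adjacency between neighborhood cells
  bool inN18[27];          // |dx|+|dy|+|dz| in {1, 2}
  bool face[27];           // |dx|+|dy|+|dz| == 1
  Neigh() {
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int i = (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
          off[i][0] = dx; off[i][1] = dy; off[i][2] = dz;
          int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
          inN18[i] = (m == 1 || m == 2);
          face[i] = (m == 1);
        }
    for (int a = 0; a < 27; a++)
      for (int b = 0; b < 27; b++) {
        int ddx = std::abs(off[a][0] - off[b][0]);
        int ddy = std::abs(off[a][1] - off[b][1]);
        int ddz = std::abs(off[a][2] - off[b][2]);
        int cheb = std::max(ddx, std::max(ddy, ddz));
        adj26[a][b] = (a != b) && cheb == 1;
        adj6[a][b] = (a != b) && (ddx + ddy + ddz) == 1;
      }
  }
};

const Neigh NB;

// nb[27]: 0/1 occupancy of the 3x3x3 neighborhood (center at 13).
bool isSimple(const unsigned char nb[27]) {
  // (a) exactly one 26-component of foreground among the 26 neighbors
  bool seen[27] = {false};
  int comps = 0;
  int stack[27], top;
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    comps++;
    if (comps > 1) return false;
    top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int c = stack[--top];
      for (int t = 0; t < 27; t++) {
        if (t == 13 || seen[t] || !nb[t] || !NB.adj26[c][t]) continue;
        seen[t] = true;
        stack[top++] = t;
      }
    }
  }
  if (comps != 1) return false;

  // (b) exactly one 6-component of background in N18 touching a face neighbor
  bool seenB[27] = {false};
  int compsTouch = 0;
  for (int s = 0; s < 27; s++) {
    if (!NB.inN18[s] || nb[s] || seenB[s]) continue;
    bool touches = false;
    top = 0;
    stack[top++] = s;
    seenB[s] = true;
    while (top > 0) {
      int c = stack[--top];
      if (NB.face[c]) touches = true;
      for (int t = 0; t < 27; t++) {
        if (!NB.inN18[t] || seenB[t] || nb[t] || !NB.adj6[c][t]) continue;
        seenB[t] = true;
        stack[top++] = t;
      }
    }
    if (touches) {
      compsTouch++;
      if (compsTouch > 1) return false;
    }
  }
  return compsTouch == 1;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> img((size_t)n);
  for (R_xlen_t i = 0; i < n; i++) img[(size_t)i] = mask[i] ? 1 : 0;

  auto at = [&](int x, int y, int z) -> unsigned char {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return img[(size_t)z * nx * ny + (size_t)y * nx + x];
  };
  auto fill27 = [&](int x, int y, int z, unsigned char nb[27]) {
    int k = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++)
          nb[k++] = at(x + dx, y + dy, z + dz);
  };
  auto n26count = [&](const unsigned char nb[27]) {
    int c = 0;
    for (int k = 0; k < 27; k++) if (k != 13 && nb[k]) c++;
    return c;
  };

  // subiteration border directions: N, S, E, W, U, D
  const int dirs[6][3] = {
    {0, -1, 0}, {0, 1, 0}, {1, 0, 0}, {-1, 0, 0}, {0, 0, 1}, {0, 0, -1}
  };

  std::vector<R_xlen_t> cand;
  unsigned char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
          for (int x = 0; x < nx; x++) {
            R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
            if (!img[(size_t)i]) continue;
            if (at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            fill27(x, y, z, nb);
            int cnt = n26count(nb);
            if (cnt <= 1) continue; // endpoint or isolated voxel: keep
            if (isSimple(nb)) cand.push_back(i);
          }
      // sequential re-check: topology is preserved exactly
      for (R_xlen_t i : cand) {
        int x = (int)(i % nx);
        int y = (int)((i / nx) % ny);
        int z = (int)(i / ((R_xlen_t)nx * ny));
        fill27(x, y, z, nb);
        int cnt = n26count(nb);
        if (cnt <= 1) continue;
        if (!isSimple(nb)) continue;
        img[(size_t)i] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = img[(size_t)i] != 0;
  return out;
}
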