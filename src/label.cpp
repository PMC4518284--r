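#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labeling by breadth-first search, labels assigned
// in raster-scan order of each component's first voxel (deterministic).
// connectivity: 6 (faces), 18 (faces+edges), 26 (all).
//' @noRd
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n); // zero-initialized

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; cz++)
    for (int cy = -1; cy <= 1; cy++)
      for (int cx = -1; cx <= 1; cx++) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int noff = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int lab = 0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[i] || labels[i] != 0) continue;
        lab++;
        labels[i] = lab;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cx = (int)(cur % nx);
          int cy = (int)((cur / nx) % ny);
          int cz = (int)(cur / ((R_xlen_t)nx * ny));
          for (int o = 0; o < noff; o++) {
            int X = cx + dx[o], Y = cy + dy[o], Z = cz + dz[o];
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            R_xlen_t j = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
            if (mask[j] && labels[j] == 0) {
              labels[j] = lab;
              stack.push_back(j);
            }
          }
        }
      }
  return labels;
}

// Per-voxel count of foreground 26-neighbors (0 for background voxels).
//' @noRd
// [[Rcpp::export(name = ".neighbor_count26_cpp")]]
IntegerVector neighbor_count26_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[i]) continue;
        int cnt = 0;
        for (int cz = -1; cz <= 1; cz++)
          for (int cy = -1; cy <= 1; cy++)
            for (int cx = -1; cx <= 1; cx++) {
              if (cx == 0 && cy == 0 && cz == 0) continue;
              int X = x + cx, Y = y + cy, Z = z + cz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              if (mask[(R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X]) cnt++;
            }
        out[i] = cnt;
      }
  return out;
}
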