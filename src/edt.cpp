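#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// large finite sentinel for "no seed yet"; keeps parabola arithmetic finite
static const double BIGSQ = 1e100;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower-envelope-of-parabolas method), sample spacing w
// (parabola i is f[i] + w2 * (x - i)^2, w2 = w * w).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = f[p] + w2 * (double)(q - p) * (double)(q - p);
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  // squared distance, seeded at background voxels
  std::vector<double> D((size_t)n);
  for (R_xlen_t i = 0; i < n; i++) D[(size_t)i] = mask[i] ? BIGSQ : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double w2 = spacing[0] * spacing[0];
  for (int zi = 0; zi < nz; zi++)
    for (int yi = 0; yi < ny; yi++) {
      size_t base = (size_t)zi * nx * ny + (size_t)yi * nx;
      for (int xi = 0; xi < nx; xi++) f[xi] = D[base + xi];
      dt1d(f, d, v, z, nx, w2);
      for (int xi = 0; xi < nx; xi++) D[base + xi] = d[xi];
    }

  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int zi = 0; zi < nz; zi++)
    for (int xi = 0; xi < nx; xi++) {
      size_t base = (size_t)zi * nx * ny + xi;
      for (int yi = 0; yi < ny; yi++) f[yi] = D[base + (size_t)yi * nx];
      dt1d(f, d, v, z, ny, w2);
      for (int yi = 0; yi < ny; yi++) D[base + (size_t)yi * nx] = d[yi];
    }

  // pass along z
  w2 = spacing[2] * spacing[2];
  for (int yi = 0; yi < ny; yi++)
    for (int xi = 0; xi < nx; xi++) {
      size_t base = (size_t)yi * nx + xi;
      for (int zi = 0; zi < nz; zi++) f[zi] = D[base + (size_t)zi * nx * ny];
      dt1d(f, d, v, z, nz, w2);
      for (int zi = 0; zi < nz; zi++) D[base + (size_t)zi * nx * ny] = d[zi];
    }

  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(D[(size_t)i]);
  return out;
}

// Chamfer (3,4,5) distance approximation, two raster passes over the
// 26-neighborhood; isotropic spacing only (scaled by spacing / 3).
//' @noRd
// [[Rcpp::export(name = ".chamfer3d_cpp")]]
NumericVector chamfer3d_cpp(LogicalVector mask, IntegerVector dims,
                            double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D((size_t)n);
  const double BIG = 1e30;
  for (R_xlen_t i = 0; i < n; i++) D[(size_t)i] = mask[i] ? BIG : 0.0;

  // neighbor offsets with chamfer weights 3 (face), 4 (edge), 5 (vertex)
  struct Off { int dx, dy, dz; double w; };
  std::vector<Off> fwd;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        // forward pass uses neighbors already visited in raster order
        if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) {
          int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
          double w = (m == 1) ? 3.0 : (m == 2 ? 4.0 : 5.0);
          fwd.push_back({dx, dy, dz, w});
        }
      }

  auto at = [&](int x, int y, int z) -> size_t {
    return (size_t)z * nx * ny + (size_t)y * nx + x;
  };

  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t i = at(x, y, z);
        if (D[i] == 0.0) continue;
        double best = D[i];
        for (const Off& o : fwd) {
          int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          double cand = D[at(X, Y, Z)] + o.w;
          if (cand < best) best = cand;
        }
        D[i] = best;
      }

  for (int z = nz - 1; z >= 0; z--)
    for (int y = ny - 1; y >= 0; y--)
      for (int x = nx - 1; x >= 0; x--) {
        size_t i = at(x, y, z);
        if (D[i] == 0.0) continue;
        double best = D[i];
        for (const Off& o : fwd) { // reversed offsets
          int X = x - o.dx, Y = y - o.dy, Z = z - o.dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          double cand = D[at(X, Y, Z)] + o.w;
          if (cand < best) best = cand;
        }
        D[i] = best;
      }

  NumericVector out(n);
  const double scale = spacing / 3.0;
  for (R_xlen_t i = 0; i < n; i++) out[i] = D[(size_t)i] * scale;
  return out;
}
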