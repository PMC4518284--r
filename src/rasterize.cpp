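#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Rasterize a set of tubes (polyline centerlines with constant radius per
// segment) onto a voxel grid: a voxel is foreground iff its center lies
// strictly within radius of the polyline (exact point-to-segment distance,
// physical units). Voxel centers exactly on the tube wall are excluded with
// a small symmetric tolerance, so an exact-integer-radius tube rasterizes
// to the same disc on both sides regardless of floating-point rounding (a
// radius of exactly one voxel gives a single-voxel column, the minimum
// resolvable tube). Voxel-center convention: position = 0-based index *
// spacing.

static double segDist2(double px, double py, double pz,
                       double ax, double ay, double az,
                       double bx, double by, double bz) {
  double abx = bx - ax, aby = by - ay, abz = bz - az;
  double apx = px - ax, apy = py - ay, apz = pz - az;
  double denom = abx * abx + aby * aby + abz * abz;
  double t = 0.0;
  if (denom > 0) {
    t = (apx * abx + apy * aby + apz * abz) / denom;
    t = std::max(0.0, std::min(1.0, t));
  }
  double dx = apx - t * abx, dy = apy - t * aby, dz = apz - t * abz;
  return dx * dx + dy * dy + dz * dz;
}

//' @noRd
// [[Rcpp::export(name = ".rasterize_tubes_cpp")]]
LogicalVector rasterize_tubes_cpp(IntegerVector dims, NumericVector spacing,
                                  List polylines, NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n); // FALSE-initialized
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  for (int s = 0; s < polylines.size(); s++) {
    NumericMatrix P = polylines[s];
    const double r = radii[s];
    const double r2 = r * r * (1.0 - 1e-12);
    const int np = P.nrow();
    if (np < 1) continue;
    // bounding box in voxel indices
    double lo[3] = {P(0,0), P(0,1), P(0,2)}, hi[3] = {P(0,0), P(0,1), P(0,2)};
    for (int i = 1; i < np; i++)
      for (int c = 0; c < 3; c++) {
        lo[c] = std::min(lo[c], P(i, c));
        hi[c] = std::max(hi[c], P(i, c));
      }
    int x0 = std::max(0, (int)std::floor((lo[0] - r) / sx));
    int x1 = std::min(nx - 1, (int)std::ceil((hi[0] + r) / sx));
    int y0 = std::max(0, (int)std::floor((lo[1] - r) / sy));
    int y1 = std::min(ny - 1, (int)std::ceil((hi[1] + r) / sy));
    int z0 = std::max(0, (int)std::floor((lo[2] - r) / sz));
    int z1 = std::min(nz - 1, (int)std::ceil((hi[2] + r) / sz));

    for (int z = z0; z <= z1; z++)
      for (int y = y0; y <= y1; y++)
        for (int x = x0; x <= x1; x++) {
          R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
          if (out[i]) continue;
          double px = x * sx, py = y * sy, pz = z * sz;
          bool in = false;
          if (np == 1) {
            double dx = px - P(0,0), dy = py - P(0,1), dz = pz - P(0,2);
            in = (dx*dx + dy*dy + dz*dz) < r2;
          } else {
            for (int e = 0; e + 1 < np; e++) {
              if (segDist2(px, py, pz, P(e,0), P(e,1), P(e,2),
                           P(e+1,0), P(e+1,1), P(e+1,2)) < r2) {
                in = true;
                break;
              }
            }
          }
          if (in) out[i] = true;
        }
  }
  return out;
}
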