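#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Separable Gaussian blur with half-sample symmetric ("reflect") boundary
// handling, which conserves the volume mean exactly for a normalized kernel.
// sigma is given per axis in voxels; kernels truncated at 4 sigma.

static std::vector<double> gaussKernel(double sigma, int& radius) {
  radius = (int)std::ceil(4.0 * sigma);
  if (sigma <= 0) { radius = 0; return std::vector<double>(1, 1.0); }
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; i++) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + radius] = v;
    s += v;
  }
  for (double& v : k) v /= s;
  return k;
}

// reflect index into [0, n): ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

//' @noRd
// [[Rcpp::export(name = ".gaussian_blur3d_cpp")]]
NumericVector gaussian_blur3d_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector sigmaVox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a((size_t)n), b((size_t)n);
  for (R_xlen_t i = 0; i < n; i++) a[(size_t)i] = vol[i];

  const int ns[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int axis = 0; axis < 3; axis++) {
    double sigma = sigmaVox[axis];
    if (sigma <= 0) continue;
    int radius;
    std::vector<double> k = gaussKernel(sigma, radius);
    const int len = ns[axis];
    const R_xlen_t stride = strides[axis];
    // iterate over all lines along `axis`
    const int u_n = ns[(axis + 1) % 3];
    const int v_n = ns[(axis + 2) % 3];
    const R_xlen_t u_s = strides[(axis + 1) % 3];
    const R_xlen_t v_s = strides[(axis + 2) % 3];
    for (int v = 0; v < v_n; v++)
      for (int u = 0; u < u_n; u++) {
        R_xlen_t base = (R_xlen_t)u * u_s + (R_xlen_t)v * v_s;
        for (int p = 0; p < len; p++) {
          double acc = 0.0;
          for (int j = -radius; j <= radius; j++) {
            int q = reflect(p + j, len);
            acc += k[j + radius] * a[(size_t)(base + (R_xlen_t)q * stride)];
          }
          b[(size_t)(base + (R_xlen_t)p * stride)] = acc;
        }
      }
    std::swap(a, b);
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = a[(size_t)i];
  return out;
}
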