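#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, bool *inside) {
  // 0-based continuous coordinates; zero outside the grid
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    *inside = false;
    return 0.0;
  }
  *inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  long sy = nx, sz = (long)nx * ny;
#define V(i, j, k) v[(i) + (long)(j) * sy + (long)(k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Rescale a volume onto a new grid: input coordinate = output coordinate * scale
// (0-based voxel indices, axis-aligned). Trilinear interpolation, clamped edges.
// [[Rcpp::export]]
NumericVector cpp_resample_linear(NumericVector vol, IntegerVector out_dim,
                                  NumericVector scale) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((long)ox * oy * oz);
  const double *v = vol.begin();
  long idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double x = std::min((double)(nx - 1), i * scale[0]);
        double y = std::min((double)(ny - 1), j * scale[1]);
        double z = std::min((double)(nz - 1), k * scale[2]);
        bool inside;
        out[idx++] = tri_sample(v, nx, ny, nz, x, y, z, &inside);
      }
  out.attr("dim") = out_dim;
  return out;
}

// Nearest-neighbour variant for label masks.
// [[Rcpp::export]]
IntegerVector cpp_resample_nearest(IntegerVector vol, IntegerVector out_dim,
                                   NumericVector scale) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  IntegerVector out((long)ox * oy * oz);
  long sy = nx, sz = (long)nx * ny;
  long idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        int x = std::min(nx - 1, (int)std::lround(i * scale[0]));
        int y = std::min(ny - 1, (int)std::lround(j * scale[1]));
        int z = std::min(nz - 1, (int)std::lround(k * scale[2]));
        out[idx++] = vol[x + y * sy + z * sz];
      }
  out.attr("dim") = out_dim;
  return out;
}

// Maximum-intensity projection of a cubic patch viewed under rotation R:
// the patch is resampled on its own grid as V'(p) = V(R^T (p - c) + c) and
// projected by per-ray maximum along the first array axis. Sample points
// falling outside the cube carry no structure and are ignored; a ray that
// misses the cube entirely (possible at tile corners under rotation) is
// filled with the patch minimum so every tile pixel stays within the
// patch's intensity range. Returns an S x S tile over axes 2 and 3.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_mip(NumericVector patch, NumericMatrix R) {
  IntegerVector d = patch.attr("dim");
  int S = d[0];
  const double *v = patch.begin();
  double c = (S - 1) / 2.0;
  double vmin = Rcpp::min(patch);
  NumericMatrix tile(S, S);
  for (int k = 0; k < S; ++k)
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      for (int i = 0; i < S; ++i) {
        double dx = i - c, dy = j - c, dz = k - c;
        // R^T * (p - c) + c
        double x = R(0, 0) * dx + R(1, 0) * dy + R(2, 0) * dz + c;
        double y = R(0, 1) * dx + R(1, 1) * dy + R(2, 1) * dz + c;
        double z = R(0, 2) * dx + R(1, 2) * dy + R(2, 2) * dz + c;
        bool inside;
        double s = tri_sample(v, S, S, S, x, y, z, &inside);
        if (inside && s > best) best = s;
      }
      tile(j, k) = (best == R_NegInf) ? vmin : best;
    }
  return tile;
}
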