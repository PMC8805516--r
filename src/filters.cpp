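#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sampled, sum-normalized Gaussian kernel truncated at 4 sigma.
static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// 1-D convolution along one axis with reflected boundaries.
static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int nx, int ny, int nz, const std::vector<double> &ker,
                      int axis) {
  int r = ((int)ker.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  long strides[3] = {1, (long)nx, (long)nx * ny};
  long stride = strides[axis];
  // iterate over all lines along `axis`
  int a1 = (axis == 0) ? 1 : 0;
  int a2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[a2]; ++j2) {
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      long base = (long)j1 * strides[a1] + (long)j2 * strides[a2];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ii = i + t;
          if (ii < 0) ii = -ii;                    // reflect
          if (ii >= len) ii = 2 * len - 2 - ii;
          if (ii < 0) ii = 0;                      // tiny-axis guard
          acc += ker[t + r] * in[base + (long)ii * stride];
        }
        out[base + (long)i * stride] = acc;
      }
    }
  }
}

static std::vector<double> smooth3d(const std::vector<double> &v, int nx, int ny,
                                    int nz, double sigma) {
  std::vector<double> a(v.size()), b(v.size());
  std::vector<double> k = gauss_kernel(sigma);
  conv_axis(v, a, nx, ny, nz, k, 0);
  conv_axis(a, b, nx, ny, nz, k, 1);
  conv_axis(b, a, nx, ny, nz, k, 2);
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth3d(NumericVector vol, double sigma_vox) {
  IntegerVector d = vol.attr("dim");
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> s = smooth3d(v, d[0], d[1], d[2], sigma_vox);
  NumericVector out(s.begin(), s.end());
  out.attr("dim") = d;
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix (closed-form trigonometric method).
static inline void sym3_eigenvalues(double a11, double a22, double a33,
                                    double a12, double a13, double a23,
                                    double eig[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    eig[0] = a11; eig[1] = a22; eig[2] = a33;
    return;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
              (a33 - q) * (a33 - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  eig[0] = e1; eig[1] = 3.0 * q - e1 - e3; eig[2] = e3;
}

// Single-scale selective-enhancement responses (blob / line / plane) from the
// Hessian of the sigma-smoothed volume. Derivatives are central differences on
// the smoothed grid; responses are sigma^2-normalized; eigenvalues ordered
// |l1| >= |l2| >= |l3|. One-voxel border is left at zero.
// [[Rcpp::export]]
List cpp_shape_responses(NumericVector vol, double sigma_vox) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> s = smooth3d(v, nx, ny, nz, sigma_vox);
  NumericVector blob(v.size()), line(v.size()), plane(v.size());
  const double eps = 1e-12;
  double s2 = sigma_vox * sigma_vox;
  long sx = 1, sy = nx, sz = (long)nx * ny;
  for (int k = 1; k < nz - 1; ++k) {
    for (int j = 1; j < ny - 1; ++j) {
      for (int i = 1; i < nx - 1; ++i) {
        long c = i + (long)j * sy + (long)k * sz;
        double f = s[c];
        double hxx = s[c + sx] - 2 * f + s[c - sx];
        double hyy = s[c + sy] - 2 * f + s[c - sy];
        double hzz = s[c + sz] - 2 * f + s[c - sz];
        double hxy = (s[c + sx + sy] - s[c + sx - sy] - s[c - sx + sy] + s[c - sx - sy]) / 4.0;
        double hxz = (s[c + sx + sz] - s[c + sx - sz] - s[c - sx + sz] + s[c - sx - sz]) / 4.0;
        double hyz = (s[c + sy + sz] - s[c + sy - sz] - s[c - sy + sz] + s[c - sy - sz]) / 4.0;
        double eig[3];
        sym3_eigenvalues(hxx, hyy, hzz, hxy, hxz, hyz, eig);
        // order by descending magnitude
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2 - a; ++b)
            if (std::fabs(eig[b]) < std::fabs(eig[b + 1])) {
              double t = eig[b]; eig[b] = eig[b + 1]; eig[b + 1] = t;
            }
        double l1 = eig[0], l2 = eig[1], l3 = eig[2];
        double a1 = std::fabs(l1), a2 = std::fabs(l2), a3 = std::fabs(l3);
        if (l1 < 0 && l2 < 0 && l3 < 0)
          blob[c] = s2 * a3 * a3 / (a1 + eps);
        if (l1 < 0 && l2 < 0)
          line[c] = s2 * a2 * (a2 - a3) / (a1 + eps);
        if (l1 < 0)
          plane[c] = s2 * (a1 - a2);
      }
    }
  }
  blob.attr("dim") = d; line.attr("dim") = d; plane.attr("dim") = d;
  return List::create(_["blob"] = blob, _["line"] = line, _["plane"] = plane);
}

// 26-neighborhood local maxima of `resp` inside `mask`, above `min_response`.
// Returns 1-based voxel coordinates and values, unsorted.
// [[Rcpp::export]]
List cpp_local_maxima(NumericVector resp, LogicalVector mask, double min_response) {
  IntegerVector d = resp.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  long sy = nx, sz = (long)nx * ny;
  std::vector<int> ci, cj, ck;
  std::vector<double> val;
  for (int k = 1; k < nz - 1; ++k) {
    for (int j = 1; j < ny - 1; ++j) {
      for (int i = 1; i < nx - 1; ++i) {
        long c = i + (long)j * sy + (long)k * sz;
        if (!mask[c]) continue;
        double v = resp[c];
        if (!(v > min_response)) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (resp[c + di + (long)dj * sy + (long)dk * sz] > v) { ismax = false; break; }
            }
        if (ismax) { ci.push_back(i + 1); cj.push_back(j + 1); ck.push_back(k + 1); val.push_back(v); }
      }
    }
  }
  int n = ci.size();
  IntegerMatrix coords(n, 3);
  NumericVector values(n);
  for (int t = 0; t < n; ++t) {
    coords(t, 0) = ci[t]; coords(t, 1) = cj[t]; coords(t, 2) = ck[t];
    values[t] = val[t];
  }
  return List::create(_["coords"] = coords, _["values"] = values);
}
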