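#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Convolution kernels for the network branches. Tensor layouts (column-major,
// as produced by base R `array`):
//   2-D activations: (H, W, C, N)     weights: (k, k, Cin, Cout)
//   3-D activations: (D, H, W, C, N)  weights: (k, k, k, Cin, Cout)
// `pad` is symmetric zero padding, `stride` the subsampling step.

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  int k = dw[0], Co = dw[3];
  int Ho = out_len(H, k, stride, pad), Wo = out_len(W, k, stride, pad);
  NumericVector y((long)Ho * Wo * Co * N);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  long xs1 = H, xs2 = (long)H * W, xs3 = (long)H * W * Ci;
  long ws1 = k, ws2 = (long)k * k, ws3 = (long)k * k * Ci;
  long ys1 = Ho, ys2 = (long)Ho * Wo, ys3 = (long)Ho * Wo * Co;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = pb[co];
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < Ci; ++ci)
            for (int kw = 0; kw < k; ++kw) {
              int wi = w0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                int hi = h0 + kh;
                if (hi < 0 || hi >= H) continue;
                acc += px[hi + wi * xs1 + ci * xs2 + n * xs3] *
                       pw[kh + kw * ws1 + ci * ws2 + co * ws3];
              }
            }
          py[ho + wo * ys1 + co * ys2 + n * ys3] = acc;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dy = gy.attr("dim");
  int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  int k = dw[0], Co = dw[3];
  int Ho = dy[0], Wo = dy[1];
  NumericVector gx((long)H * W * Ci * N), gw((long)k * k * Ci * Co), gb(Co);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  long xs1 = H, xs2 = (long)H * W, xs3 = (long)H * W * Ci;
  long ws1 = k, ws2 = (long)k * k, ws3 = (long)k * k * Ci;
  long ys1 = Ho, ys2 = (long)Ho * Wo, ys3 = (long)Ho * Wo * Co;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = pgy[ho + wo * ys1 + co * ys2 + n * ys3];
          pgb[co] += g;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < Ci; ++ci)
            for (int kw = 0; kw < k; ++kw) {
              int wi = w0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                int hi = h0 + kh;
                if (hi < 0 || hi >= H) continue;
                long xi = hi + wi * xs1 + ci * xs2 + n * xs3;
                long wix = kh + kw * ws1 + ci * ws2 + co * ws3;
                pgx[xi] += g * pw[wix];
                pgw[wix] += g * px[xi];
              }
            }
        }
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int D = dx[0], H = dx[1], W = dx[2], Ci = dx[3], N = dx[4];
  int k = dw[0], Co = dw[4];
  int Do = out_len(D, k, stride, pad), Ho = out_len(H, k, stride, pad),
      Wo = out_len(W, k, stride, pad);
  NumericVector y((long)Do * Ho * Wo * Co * N);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  long xs1 = D, xs2 = (long)D * H, xs3 = (long)D * H * W, xs4 = xs3 * Ci;
  long ws1 = k, ws2 = (long)k * k, ws3 = (long)k * k * k, ws4 = ws3 * Ci;
  long ys1 = Do, ys2 = (long)Do * Ho, ys3 = (long)Do * Ho * Wo, ys4 = ys3 * Co;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int dc = 0; dc < Do; ++dc) {
            double acc = pb[co];
            int d0 = dc * stride - pad, h0 = ho * stride - pad, w0 = wo * stride - pad;
            for (int ci = 0; ci < Ci; ++ci)
              for (int kw = 0; kw < k; ++kw) {
                int wi = w0 + kw;
                if (wi < 0 || wi >= W) continue;
                for (int kh = 0; kh < k; ++kh) {
                  int hi = h0 + kh;
                  if (hi < 0 || hi >= H) continue;
                  for (int kd = 0; kd < k; ++kd) {
                    int di = d0 + kd;
                    if (di < 0 || di >= D) continue;
                    acc += px[di + hi * xs1 + wi * xs2 + ci * xs3 + n * xs4] *
                           pw[kd + kh * ws1 + kw * ws2 + ci * ws3 + co * ws4];
                  }
                }
              }
            py[dc + ho * ys1 + wo * ys2 + co * ys3 + n * ys4] = acc;
          }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dy = gy.attr("dim");
  int D = dx[0], H = dx[1], W = dx[2], Ci = dx[3], N = dx[4];
  int k = dw[0], Co = dw[4];
  int Do = dy[0], Ho = dy[1], Wo = dy[2];
  NumericVector gx((long)D * H * W * Ci * N), gw((long)k * k * k * Ci * Co), gb(Co);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  long xs1 = D, xs2 = (long)D * H, xs3 = (long)D * H * W, xs4 = xs3 * Ci;
  long ws1 = k, ws2 = (long)k * k, ws3 = (long)k * k * k, ws4 = ws3 * Ci;
  long ys1 = Do, ys2 = (long)Do * Ho, ys3 = (long)Do * Ho * Wo, ys4 = ys3 * Co;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int dc = 0; dc < Do; ++dc) {
            double g = pgy[dc + ho * ys1 + wo * ys2 + co * ys3 + n * ys4];
            pgb[co] += g;
            int d0 = dc * stride - pad, h0 = ho * stride - pad, w0 = wo * stride - pad;
            for (int ci = 0; ci < Ci; ++ci)
              for (int kw = 0; kw < k; ++kw) {
                int wi = w0 + kw;
                if (wi < 0 || wi >= W) continue;
                for (int kh = 0; kh < k; ++kh) {
                  int hi = h0 + kh;
                  if (hi < 0 || hi >= H) continue;
                  for (int kd = 0; kd < k; ++kd) {
                    int di = d0 + kd;
                    if (di < 0 || di >= D) continue;
                    long xi = di + hi * xs1 + wi * xs2 + ci * xs3 + n * xs4;
                    long wix = kd + kh * ws1 + kw * ws2 + ci * ws3 + co * ws4;
                    pgx[xi] += g * pw[wix];
                    pgw[wix] += g * px[xi];
                  }
                }
              }
          }
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
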