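// Low-level CPU kernels for the detection network: im2col/col2im
// convolution lowering, stride-1 same-padded max pooling (spatial pyramid
// pooling), 2x bilinear upsampling and 2x average pooling, each with the
// adjoint needed for reverse-mode training. Tensors are R arrays laid out
// (H, W, C, N), column-major.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int KH, int KW, int SH, int SW,
                         int PH, int PW, int DH, int DW) {
  const int Hout = (H + 2 * PH - DH * (KH - 1) - 1) / SH + 1;
  const int Wout = (W + 2 * PW - DW * (KW - 1) - 1) / SW + 1;
  NumericMatrix out(KH * KW * C, Hout * Wout * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int K = KH * KW * C;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho) {
        const R_xlen_t col = ho + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
        double* o = op + col * K;
        for (int c = 0; c < C; ++c)
          for (int kw = 0; kw < KW; ++kw) {
            const int wi = wo * SW - PW + kw * DW;
            for (int kh = 0; kh < KH; ++kh) {
              const int hi = ho * SH - PH + kh * DH;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = xp[hi + (R_xlen_t)H * (wi + (R_xlen_t)W * (c + (R_xlen_t)C * n))];
              o[kh + KH * (kw + KW * c)] = v;
            }
          }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int KH, int KW, int SH, int SW,
                         int PH, int PW, int DH, int DW) {
  const int Hout = (H + 2 * PH - DH * (KH - 1) - 1) / SH + 1;
  const int Wout = (W + 2 * PW - DW * (KW - 1) - 1) / SW + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const int K = KH * KW * C;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho) {
        const R_xlen_t col = ho + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
        const double* o = cp + col * K;
        for (int c = 0; c < C; ++c)
          for (int kw = 0; kw < KW; ++kw) {
            const int wi = wo * SW - PW + kw * DW;
            for (int kh = 0; kh < KH; ++kh) {
              const int hi = ho * SH - PH + kh * DH;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                xp[hi + (R_xlen_t)H * (wi + (R_xlen_t)W * (c + (R_xlen_t)C * n))] +=
                  o[kh + KH * (kw + KW * c)];
            }
          }
      }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Stride-1 max pooling with same padding (odd kernel). Returns the pooled
// values and the flat input index of each maximum for the adjoint.
// [[Rcpp::export]]
List maxpool_same_cpp(NumericVector x, int H, int W, int C, int N, int K) {
  const int P = K / 2;
  NumericVector out((R_xlen_t)H * W * C * N);
  IntegerVector arg((R_xlen_t)H * W * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double best = R_NegInf; R_xlen_t bi = -1;
          const int w0 = std::max(0, w - P), w1 = std::min(W - 1, w + P);
          const int h0 = std::max(0, h - P), h1 = std::min(H - 1, h + P);
          for (int wi = w0; wi <= w1; ++wi)
            for (int hi = h0; hi <= h1; ++hi) {
              const R_xlen_t idx = base + hi + (R_xlen_t)H * wi;
              if (xp[idx] > best) { best = xp[idx]; bi = idx; }
            }
          const R_xlen_t oi = base + h + (R_xlen_t)H * w;
          out[oi] = best; arg[oi] = (int)bi;
        }
    }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_same_grad_cpp(NumericVector g, IntegerVector arg,
                                    int H, int W, int C, int N) {
  NumericVector gx((R_xlen_t)H * W * C * N);
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[arg[i]] += g[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

static inline void bilin_coef(int o, int S, int& i0, int& i1, double& w1) {
  // output o maps to input (o + 0.5)/2 - 0.5 (half-pixel centers)
  double src = (o + 0.5) / 2.0 - 0.5;
  int f = (int)std::floor(src);
  w1 = src - f;
  i0 = std::min(std::max(f, 0), S - 1);
  i1 = std::min(std::max(f + 1, 0), S - 1);
}

// [[Rcpp::export]]
NumericVector bilinear2x_cpp(NumericVector x, int H, int W, int C, int N) {
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((R_xlen_t)H2 * W2 * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t bi = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const R_xlen_t bo = (R_xlen_t)H2 * W2 * (c + (R_xlen_t)C * n);
      for (int w = 0; w < W2; ++w) {
        int w0, w1; double ww;
        bilin_coef(w, W, w0, w1, ww);
        for (int h = 0; h < H2; ++h) {
          int h0, h1; double hw;
          bilin_coef(h, H, h0, h1, hw);
          const double v =
            (1 - hw) * (1 - ww) * xp[bi + h0 + (R_xlen_t)H * w0] +
            hw * (1 - ww) * xp[bi + h1 + (R_xlen_t)H * w0] +
            (1 - hw) * ww * xp[bi + h0 + (R_xlen_t)H * w1] +
            hw * ww * xp[bi + h1 + (R_xlen_t)H * w1];
          out[bo + h + (R_xlen_t)H2 * w] = v;
        }
      }
    }
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector bilinear2x_grad_cpp(NumericVector g, int H, int W, int C, int N) {
  // H, W are the *input* (coarse) sizes; g has size (2H, 2W, C, N)
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector gx((R_xlen_t)H * W * C * N);
  const double* gp = g.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t bi = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const R_xlen_t bo = (R_xlen_t)H2 * W2 * (c + (R_xlen_t)C * n);
      for (int w = 0; w < W2; ++w) {
        int w0, w1; double ww;
        bilin_coef(w, W, w0, w1, ww);
        for (int h = 0; h < H2; ++h) {
          int h0, h1; double hw;
          bilin_coef(h, H, h0, h1, hw);
          const double gv = gp[bo + h + (R_xlen_t)H2 * w];
          gx[bi + h0 + (R_xlen_t)H * w0] += (1 - hw) * (1 - ww) * gv;
          gx[bi + h1 + (R_xlen_t)H * w0] += hw * (1 - ww) * gv;
          gx[bi + h0 + (R_xlen_t)H * w1] += (1 - hw) * ww * gv;
          gx[bi + h1 + (R_xlen_t)H * w1] += hw * ww * gv;
        }
      }
    }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// [[Rcpp::export]]
NumericVector avgpool2x_cpp(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t bi = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const R_xlen_t bo = (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          out[bo + h + (R_xlen_t)Ho * w] = 0.25 * (
            xp[bi + 2 * h + (R_xlen_t)H * (2 * w)] +
            xp[bi + 2 * h + 1 + (R_xlen_t)H * (2 * w)] +
            xp[bi + 2 * h + (R_xlen_t)H * (2 * w + 1)] +
            xp[bi + 2 * h + 1 + (R_xlen_t)H * (2 * w + 1)]);
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool2x_grad_cpp(NumericVector g, int H, int W, int C, int N) {
  // H, W are the *input* sizes; g has size (H/2, W/2, C, N)
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  const double* gp = g.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t bi = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const R_xlen_t bo = (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double gv = 0.25 * gp[bo + h + (R_xlen_t)Ho * w];
          gx[bi + 2 * h + (R_xlen_t)H * (2 * w)] += gv;
          gx[bi + 2 * h + 1 + (R_xlen_t)H * (2 * w)] += gv;
          gx[bi + 2 * h + (R_xlen_t)H * (2 * w + 1)] += gv;
          gx[bi + 2 * h + 1 + (R_xlen_t)H * (2 * w + 1)] += gv;
        }
    }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
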