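#include <Rcpp.h>
using namespace Rcpp;

// Dense-layer plumbing for the conv-net engine. Images travel as 4-D arrays
// dim = (H, W, C, N), column-major. im2col rows are ordered (oy fastest,
// then ox, then n); columns are (ky fastest, then kx, then channel), so a
// convolution is a single BLAS matmul on the R side. col2im is the exact
// adjoint (scatter-add), which is what both the conv backward-data pass and
// the transposed-convolution forward pass need.

// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, int H, int W, int C, int N,
                        int k, int stride, int pad, int oh, int ow) {
  NumericMatrix out(oh * ow * N, k * k * C);
  double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  for (int ch = 0; ch < C; ++ch) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        R_xlen_t col = ky + k * (kx + (R_xlen_t)k * ch);
        double* dst = op + col * nrow;
        for (int n = 0; n < N; ++n) {
          R_xlen_t xoff = ((R_xlen_t)n * C + ch) * H * W;
          for (int ox = 0; ox < ow; ++ox) {
            int ix = ox * stride + kx - pad;
            R_xlen_t r0 = (R_xlen_t)oh * (ox + (R_xlen_t)ow * n);
            if (ix < 0 || ix >= W) {
              for (int oy = 0; oy < oh; ++oy) dst[r0 + oy] = 0.0;
              continue;
            }
            double* src = xp + xoff + (R_xlen_t)ix * H;
            for (int oy = 0; oy < oh; ++oy) {
              int iy = oy * stride + ky - pad;
              dst[r0 + oy] = (iy < 0 || iy >= H) ? 0.0 : src[iy];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, int H, int W, int C, int N,
                        int k, int stride, int pad, int oh, int ow) {
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = REAL(x);
  double* cp = REAL(cols);
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  for (int ch = 0; ch < C; ++ch) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        R_xlen_t col = ky + k * (kx + (R_xlen_t)k * ch);
        double* src = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          R_xlen_t xoff = ((R_xlen_t)n * C + ch) * H * W;
          for (int ox = 0; ox < ow; ++ox) {
            int ix = ox * stride + kx - pad;
            if (ix < 0 || ix >= W) continue;
            R_xlen_t r0 = (R_xlen_t)oh * (ox + (R_xlen_t)ow * n);
            double* dst = xp + xoff + (R_xlen_t)ix * H;
            for (int oy = 0; oy < oh; ++oy) {
              int iy = oy * stride + ky - pad;
              if (iy >= 0 && iy < H) dst[iy] += src[r0 + oy];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// 2x2 (or p x p) max pooling, stride = pool size; returns pooled values and
// the flat index of each argmax so the backward pass is a plain scatter.
// [[Rcpp::export]]
List nn_maxpool(NumericVector x, int H, int W, int C, int N, int p) {
  int oh = H / p, ow = W / p;
  R_xlen_t n_out = (R_xlen_t)oh * ow * C * N;
  NumericVector y(n_out);
  IntegerVector idx(n_out);  // 1-based flat index into x
  double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      R_xlen_t base = ((R_xlen_t)n * C + ch) * H * W;
      for (int ox = 0; ox < ow; ++ox) {
        for (int oy = 0; oy < oh; ++oy) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int dx = 0; dx < p; ++dx) {
            R_xlen_t coloff = base + (R_xlen_t)(ox * p + dx) * H + oy * p;
            for (int dy = 0; dy < p; ++dy) {
              double v = xp[coloff + dy];
              if (v > best) { best = v; bi = coloff + dy; }
            }
          }
          // output laid out (oh, ow, C, N) to match the array convention
          R_xlen_t oi = (R_xlen_t)oy + oh * (ox + (R_xlen_t)ow * (ch + (R_xlen_t)C * n));
          yp[oi] = best;
          ip[oi] = (int)(bi + 1);
          ++o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_backward(NumericVector dy, IntegerVector idx,
                                  int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* dxp = REAL(dx);
  double* dyp = REAL(dy);
  int* ip = INTEGER(idx);
  R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i] - 1] += dyp[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
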