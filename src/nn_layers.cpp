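// Fused conv / transposed-conv layer passes: im2col (or its col2im adjoint)
// plus the BLAS matmul and ReLU in one call, avoiding R-side permutations.
// Arrays are (H, W, C, N) column-major; the im2col row order is
// (oy fastest, ox, n), columns (ky, kx, channel), so for a fixed channel c
// and image n both the array slice and the flat matrix block are contiguous
// and conversion is a memcpy.
//
// The im2col buffers run to hundreds of megabytes per minibatch; allocating
// them afresh every call costs more in page faults than the matmuls do in
// arithmetic (glibc hands such blocks straight back to the kernel). They
// therefore live in a small persistent pool keyed by a caller-chosen slot:
// successive minibatches have identical shapes, so after the first batch
// the pool is allocation-free.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<arma::mat>& buffer_pool() {
  static std::vector<arma::mat> pool(32);
  return pool;
}

static arma::mat& pool_mat(int slot, arma::uword nr, arma::uword nc) {
  arma::mat& m = buffer_pool()[slot];
  m.set_size(nr, nc);  // no-op when the shape is unchanged
  return m;
}

// [[Rcpp::export]]
void nn_release_buffers() {
  for (arma::mat& m : buffer_pool()) m.reset();
}

static void im2col_fill(const double* xp, arma::mat& cols,
                        int H, int W, int C, int N,
                        int k, int stride, int pad, int oh, int ow) {
  for (int ch = 0; ch < C; ++ch) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        arma::uword col = ky + (arma::uword)k * (kx + (arma::uword)k * ch);
        double* dst = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* xoff = xp + ((arma::uword)n * C + ch) * H * W;
          for (int ox = 0; ox < ow; ++ox) {
            int ix = ox * stride + kx - pad;
            arma::uword r0 = (arma::uword)oh * (ox + (arma::uword)ow * n);
            if (ix < 0 || ix >= W) {
              std::fill(dst + r0, dst + r0 + oh, 0.0);
              continue;
            }
            const double* src = xoff + (arma::uword)ix * H;
            int iy = ky - pad;
            // valid oy range, so the hot middle is branch-free
            int lo = std::max(0, (pad - ky + stride - 1) / stride);
            int hi = std::min(oh - 1, (H - 1 - ky + pad) / stride);
            for (int oy = 0; oy < lo; ++oy) dst[r0 + oy] = 0.0;
            if (stride == 1) {
              std::copy(src + lo + iy, src + hi + 1 + iy, dst + r0 + lo);
            } else {
              for (int oy = lo; oy <= hi; ++oy) {
                dst[r0 + oy] = src[oy * stride + iy];
              }
            }
            for (int oy = hi + 1; oy < oh; ++oy) dst[r0 + oy] = 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, double* xp,
                       int H, int W, int C, int N,
                       int k, int stride, int pad, int oh, int ow) {
  for (int ch = 0; ch < C; ++ch) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        arma::uword col = ky + (arma::uword)k * (kx + (arma::uword)k * ch);
        const double* src = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* xoff = xp + ((arma::uword)n * C + ch) * H * W;
          for (int ox = 0; ox < ow; ++ox) {
            int ix = ox * stride + kx - pad;
            if (ix < 0 || ix >= W) continue;
            arma::uword r0 = (arma::uword)oh * (ox + (arma::uword)ow * n);
            double* dst = xoff + (arma::uword)ix * H;
            int iy = ky - pad;
            int lo = std::max(0, (pad - ky + stride - 1) / stride);
            int hi = std::min(oh - 1, (H - 1 - ky + pad) / stride);
            for (int oy = lo; oy <= hi; ++oy) {
              dst[oy * stride + iy] += src[r0 + oy];
            }
          }
        }
      }
    }
  }
}

// (rows = H*W per (c, n) block) flat matrix <-> (H, W, C, N) array
static void flat_to_array(const arma::mat& m, double* xp,
                          arma::uword HW, int C, int N) {
  for (int ch = 0; ch < C; ++ch) {
    const double* src = m.colptr(ch);
    for (int n = 0; n < N; ++n) {
      std::copy(src + (arma::uword)n * HW, src + ((arma::uword)n + 1) * HW,
                xp + ((arma::uword)n * C + ch) * HW);
    }
  }
}

static void array_to_flat(const double* xp, arma::mat& m,
                          arma::uword HW, int C, int N) {
  for (int ch = 0; ch < C; ++ch) {
    double* dst = m.colptr(ch);
    for (int n = 0; n < N; ++n) {
      const double* src = xp + ((arma::uword)n * C + ch) * HW;
      std::copy(src, src + HW, dst + (arma::uword)n * HW);
    }
  }
}

static NumericVector make_array(arma::uword H, arma::uword W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create((int)H, (int)W, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector conv_layer_fwd(NumericVector x, NumericMatrix Wm,
                             NumericVector b,
                             int H, int W, int C, int N, int k, int pad,
                             bool relu, int slot) {
  int Cout = Wm.ncol();
  arma::mat& cols = pool_mat(slot, (arma::uword)H * W * N,
                             (arma::uword)k * k * C);
  im2col_fill(REAL(x), cols, H, W, C, N, k, 1, pad, H, W);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat& yf = pool_mat(slot + 8, cols.n_rows, (arma::uword)Cout);
  yf = cols * Wa;
  for (int c = 0; c < Cout; ++c) yf.col(c) += b[c];
  if (relu) yf.transform([](double v) { return v > 0.0 ? v : 0.0; });
  NumericVector y = make_array(H, W, Cout, N);
  flat_to_array(yf, REAL(y), (arma::uword)H * W, Cout, N);
  return y;
}

// uses the cols buffer left in `slot` by the matching forward call
// [[Rcpp::export]]
List conv_layer_bwd(NumericMatrix Wm, NumericVector y, NumericVector dy,
                    int H, int W, int C, int N, int k, int pad,
                    bool relu, int slot) {
  int Cout = Wm.ncol();
  arma::uword HW = (arma::uword)H * W;
  arma::mat& dyf = pool_mat(slot + 8, HW * N, (arma::uword)Cout);
  array_to_flat(REAL(dy), dyf, HW, Cout, N);
  if (relu) {
    const double* yp = REAL(y);
    double* dp = dyf.memptr();
    arma::mat ymask(HW * N, Cout);
    array_to_flat(yp, ymask, HW, Cout, N);
    const double* mp = ymask.memptr();
    for (arma::uword i = 0; i < dyf.n_elem; ++i) {
      if (mp[i] <= 0.0) dp[i] = 0.0;
    }
  }
  arma::mat& cols = buffer_pool()[slot];
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat dW = cols.t() * dyf;
  arma::rowvec db = arma::sum(dyf, 0);
  arma::mat& dcols = pool_mat(slot + 16, cols.n_rows, cols.n_cols);
  dcols = dyf * Wa.t();
  NumericVector dx = make_array(H, W, C, N);
  col2im_add(dcols, REAL(dx), H, W, C, N, k, 1, pad, H, W);
  return List::create(_["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// transposed convolution: weights in the layout of the associated
// downsampling conv, (k*k*Cout) x Cin; output side = input side * stride
// [[Rcpp::export]]
NumericVector tconv_layer_fwd(NumericVector x, NumericMatrix Wm,
                              NumericVector b,
                              int H, int W, int C, int N, int k, int stride,
                              int pad, bool relu, int slot) {
  int Hb = H * stride, Wb = W * stride;
  int Cout = Wm.nrow() / (k * k);
  arma::uword HW = (arma::uword)H * W;
  arma::mat& xf = pool_mat(slot, HW * N, (arma::uword)C);
  array_to_flat(REAL(x), xf, HW, C, N);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat& ycols = pool_mat(slot + 8, HW * N, (arma::uword)k * k * Cout);
  ycols = xf * Wa.t();
  NumericVector y = make_array(Hb, Wb, Cout, N);
  col2im_add(ycols, REAL(y), Hb, Wb, Cout, N, k, stride, pad, H, W);
  double* yp = REAL(y);
  arma::uword HWb = (arma::uword)Hb * Wb;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Cout; ++c) {
      double* blk = yp + ((arma::uword)n * Cout + c) * HWb;
      double bc = b[c];
      if (relu) {
        for (arma::uword i = 0; i < HWb; ++i) {
          double v = blk[i] + bc;
          blk[i] = v > 0.0 ? v : 0.0;
        }
      } else {
        for (arma::uword i = 0; i < HWb; ++i) blk[i] += bc;
      }
    }
  }
  return y;
}

// uses the xf buffer left in `slot` by the matching forward call
// [[Rcpp::export]]
List tconv_layer_bwd(NumericMatrix Wm, NumericVector y, NumericVector dy,
                     int H, int W, int C, int N, int k, int stride, int pad,
                     bool relu, int slot) {
  int Hb = H * stride, Wb = W * stride;
  int Cout = Wm.nrow() / (k * k);
  arma::uword HWb = (arma::uword)Hb * Wb;
  // mask dy through the ReLU using the stored output, then db per channel
  NumericVector dym = clone(dy);
  double* dp = REAL(dym);
  const double* yp = REAL(y);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Cout; ++c) {
      double* blk = dp + ((arma::uword)n * Cout + c) * HWb;
      const double* yblk = yp + ((arma::uword)n * Cout + c) * HWb;
      double s = 0.0;
      for (arma::uword i = 0; i < HWb; ++i) {
        if (relu && yblk[i] <= 0.0) blk[i] = 0.0;
        s += blk[i];
      }
      db[c] += s;
    }
  }
  arma::uword HW = (arma::uword)H * W;
  arma::mat& dycols = pool_mat(slot + 16, HW * N, (arma::uword)k * k * Cout);
  im2col_fill(dp, dycols, Hb, Wb, Cout, N, k, stride, pad, H, W);
  arma::mat& xf = buffer_pool()[slot];  // left by the forward pass
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat& dxf = pool_mat(slot + 24, HW * N, (arma::uword)C);
  dxf = dycols * Wa;
  arma::mat dW = dycols.t() * xf;
  NumericVector dx = make_array(H, W, C, N);
  flat_to_array(dxf, REAL(dx), HW, C, N);
  return List::create(_["dW"] = wrap(dW),
                      _["db"] = db,
                      _["dx"] = dx);
}
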