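// Compute kernels for the segmentation network: im2col/col2im convolution,
// transposed convolution, bilinear resampling, affine warps and an exact
// Euclidean distance transform.  Feature maps are R arrays laid out
// column-major as (height, width, channel, batch); convolution weights as
// (kh, kw, c_in, c_out); transposed-convolution weights as (kh, kw, c_out,
// c_in).  Everything is templated on the scalar type so the same code path
// serves fast single-precision training and double-precision gradient
// checks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Batched im2col in transposed layout: colT is (N*Ho*Wo) x (kh*kw*C), row
// index n*Ho*Wo + oi + Ho*oj, column index ki + kh*(kj + kw*c).  Writing
// runs down contiguous rows for fixed column, matching the source stride.
template <typename eT>
static void im2colT(const double* x, int H, int W, int C, int N,
                    int kh, int kw, int stride, int pad,
                    arma::Mat<eT>& colT) {
  const int Ho = out_extent(H, kh, stride, pad);
  const int Wo = out_extent(W, kw, stride, pad);
  colT.set_size((std::size_t)N * Ho * Wo, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        eT* dst0 = colT.colptr(ki + kh * (kj + kw * c));
        const int i0 = std::max(0, (pad - ki + stride - 1) / stride);
        const int i1 = std::min(Ho, (H - 1 - ki + pad) / stride + 1);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + ((std::size_t)n * C + c) * H * W;
          eT* dstn = dst0 + (std::size_t)n * Ho * Wo;
          for (int oj = 0; oj < Wo; ++oj) {
            const int j = oj * stride + kj - pad;
            eT* dst = dstn + (std::size_t)oj * Ho;
            if (j < 0 || j >= W) {
              std::fill(dst, dst + Ho, (eT)0);
              continue;
            }
            const double* src = xc + (std::size_t)j * H;
            for (int oi = 0; oi < i0; ++oi) dst[oi] = (eT)0;
            if (stride == 1) {
              const double* s = src + i0 + ki - pad;
              for (int oi = i0; oi < i1; ++oi) dst[oi] = (eT)s[oi - i0];
            } else {
              for (int oi = i0; oi < i1; ++oi) {
                dst[oi] = (eT)src[oi * stride + ki - pad];
              }
            }
            for (int oi = std::max(i0, i1); oi < Ho; ++oi) dst[oi] = (eT)0;
          }
        }
      }
    }
  }
}

// Adjoint of im2colT: scatter-add colT back onto images.
template <typename eT>
static void col2imT(const arma::Mat<eT>& colT, int H, int W, int C, int N,
                    int kh, int kw, int stride, int pad, double* x) {
  const int Ho = out_extent(H, kh, stride, pad);
  const int Wo = out_extent(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const eT* src0 = colT.colptr(ki + kh * (kj + kw * c));
        for (int n = 0; n < N; ++n) {
          double* xc = x + ((std::size_t)n * C + c) * H * W;
          const eT* srcn = src0 + (std::size_t)n * Ho * Wo;
          for (int oj = 0; oj < Wo; ++oj) {
            const int j = oj * stride + kj - pad;
            if (j < 0 || j >= W) continue;
            double* dst = xc + (std::size_t)j * H;
            const eT* src = srcn + (std::size_t)oj * Ho;
            const int i0 = std::max(0, (pad - ki + stride - 1) / stride);
            const int i1 = std::min(Ho, (H - 1 - ki + pad) / stride + 1);
            for (int oi = i0; oi < i1; ++oi) {
              dst[oi * stride + ki - pad] += (double)src[oi];
            }
          }
        }
      }
    }
  }
}

// gather (Ho,Wo,Co,N) array into (N*Ho*Wo) x Co matrix and back
template <typename eT>
static void gatherT(const double* y, int HW, int Co, int N, arma::Mat<eT>& M) {
  M.set_size((std::size_t)N * HW, Co);
  for (int o = 0; o < Co; ++o) {
    eT* dst = M.colptr(o);
    for (int n = 0; n < N; ++n) {
      const double* src = y + ((std::size_t)n * Co + o) * HW;
      eT* d = dst + (std::size_t)n * HW;
      for (int p = 0; p < HW; ++p) d[p] = (eT)src[p];
    }
  }
}

template <typename eT>
static void scatterT(const arma::Mat<eT>& M, const double* bias, int HW,
                     int Co, int N, double* y) {
  for (int o = 0; o < Co; ++o) {
    const eT* src = M.colptr(o);
    const double b = bias ? bias[o] : 0.0;
    for (int n = 0; n < N; ++n) {
      double* dst = y + ((std::size_t)n * Co + o) * HW;
      const eT* s = src + (std::size_t)n * HW;
      for (int p = 0; p < HW; ++p) dst[p] = (double)s[p] + b;
    }
  }
}

template <typename eT>
static void load_w(const NumericVector& w, int rows, int cols, arma::Mat<eT>& Wm) {
  Wm.set_size(rows, cols);
  for (std::size_t i = 0; i < Wm.n_elem; ++i) Wm[i] = (eT)w[i];
}

// ---- implicit-GEMM path for 3x3 / stride-1 / pad-1 convolutions ----------
// The dominant layer type.  Instead of materializing the 9x-expanded im2col
// matrix, accumulate nine pointer-shifted GEMMs over the gathered activation
// matrix (N*H*W x C).  Shifted reads are wrong only on the one-pixel border
// frame of each slice, which is recomputed exactly afterwards via a small
// frame-restricted im2col.

#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
extern "C" {
void F77_NAME(sgemm)(const char* transa, const char* transb, const int* m,
                     const int* n, const int* k, const float* alpha,
                     const float* a, const int* lda, const float* b,
                     const int* ldb, const float* beta, float* c,
                     const int* ldc FCLEN FCLEN);
}

static inline void gemm_blas(char ta, char tb, int m, int n, int k,
                             double alpha, const double* A, int lda,
                             const double* B, int ldb, double beta,
                             double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}
static inline void gemm_blas(char ta, char tb, int m, int n, int k,
                             float alpha, const float* A, int lda,
                             const float* B, int ldb, float beta,
                             float* C, int ldc) {
  F77_CALL(sgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

static bool conv3_implicit(int kh, int kw, int stride, int pad, int H, int W) {
  return kh == 3 && kw == 3 && stride == 1 && pad == 1 && H >= 4 && W >= 4;
}

// row indices (into the N*H*W gathered matrix) of the one-pixel frame
static std::vector<int> frame_rows(int H, int W, int N) {
  std::vector<int> rows;
  rows.reserve((std::size_t)N * (2 * H + 2 * W - 4));
  for (int n = 0; n < N; ++n) {
    const int base = n * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        if (i == 0 || i == H - 1 || j == 0 || j == W - 1)
          rows.push_back(base + i + H * j);
  }
  return rows;
}

// frame-restricted im2col: colF (F x 9*C) from a gathered (N*H*W x C) matrix
template <typename eT>
static void im2col_frame(const arma::Mat<eT>& Xt, const std::vector<int>& rows,
                         int H, int W, arma::Mat<eT>& colF) {
  const int C = Xt.n_cols, HW = H * W;
  colF.set_size(rows.size(), 9 * C);
  for (int c = 0; c < C; ++c) {
    const eT* xc = Xt.colptr(c);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        eT* dst = colF.colptr(ki + 3 * (kj + 3 * c));
        for (std::size_t f = 0; f < rows.size(); ++f) {
          const int r = rows[f], n = r / HW, rem = r % HW;
          const int i = rem % H + ki - 1, j = rem / H + kj - 1;
          dst[f] = (i >= 0 && i < H && j >= 0 && j < W)
                       ? xc[(std::size_t)n * HW + i + H * j]
                       : (eT)0;
        }
      }
  }
}

// Y (NHW x Co) = conv3x3(Xt) with pad 1: nine shifted GEMMs + frame fix
template <typename eT>
static void conv3_fwd_core(const arma::Mat<eT>& Xt, const arma::Mat<eT>& Wm,
                           int H, int W, int N, arma::Mat<eT>& Y) {
  const int C = Xt.n_cols, Co = Wm.n_cols;
  const int NHW = N * H * W;
  Y.zeros(NHW, Co);
  arma::Mat<eT> Wk9(C, 9 * Co);
  for (int kj = 0; kj < 3; ++kj)
    for (int ki = 0; ki < 3; ++ki)
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Co; ++o)
          Wk9(c, (ki + 3 * kj) * Co + o) = Wm(ki + 3 * kj + 9 * c, o);
  // row panels keep the operands cache-resident across the nine shifts
  const int panel = std::max(H + 2, 32768 / std::max(C, 1));
  for (int r0 = 0; r0 < NHW; r0 += panel) {
    const int r1 = std::min(NHW, r0 + panel);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int off = (ki - 1) + H * (kj - 1);
        const int lo = std::max(r0, -off), hi = std::min(r1, NHW - std::max(0, off));
        if (hi <= lo) continue;
        gemm_blas('N', 'N', hi - lo, Co, C, (eT)1,
                  Xt.memptr() + lo + off, NHW, Wk9.colptr((ki + 3 * kj) * Co),
                  C, (eT)1, Y.memptr() + lo, NHW);
      }
  }
  const std::vector<int> rows = frame_rows(H, W, N);
  arma::Mat<eT> colF;
  im2col_frame<eT>(Xt, rows, H, W, colF);
  arma::Mat<eT> Yf = colF * Wm;
  for (std::size_t f = 0; f < rows.size(); ++f)
    for (int o = 0; o < Co; ++o) Y(rows[f], o) = Yf(f, o);
}

// dX (NHW x C) adjoint, dW (9C x Co), db
template <typename eT>
static void conv3_bwd_core(const arma::Mat<eT>& Xt, const arma::Mat<eT>& Wm,
                           const arma::Mat<eT>& dYt, int H, int W, int N,
                           bool need_dx, arma::Mat<eT>& dX, arma::Mat<eT>& dW,
                           arma::Col<eT>& db) {
  const int C = Xt.n_cols, Co = dYt.n_cols;
  const int NHW = N * H * W;
  const std::vector<int> rows = frame_rows(H, W, N);
  db = arma::sum(dYt, 0).t();
  // weight gradient: zero the frame rows of dY, then add exact frame terms
  arma::Mat<eT> dYz = dYt;
  for (std::size_t f = 0; f < rows.size(); ++f)
    for (int o = 0; o < Co; ++o) dYz(rows[f], o) = 0;
  dW.zeros(9 * C, Co);
  arma::Mat<eT> acc9(C, 9 * Co);
  acc9.zeros();
  const int panel = std::max(H + 2, 32768 / std::max(C, 1));
  for (int r0 = 0; r0 < NHW; r0 += panel) {
    const int r1 = std::min(NHW, r0 + panel);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int off = (ki - 1) + H * (kj - 1);
        const int lo = std::max(r0, -off), hi = std::min(r1, NHW - std::max(0, off));
        if (hi <= lo) continue;
        gemm_blas('T', 'N', C, Co, hi - lo, (eT)1,
                  Xt.memptr() + lo + off, NHW, dYz.memptr() + lo, NHW, (eT)1,
                  acc9.colptr((ki + 3 * kj) * Co), C);
      }
  }
  for (int k = 0; k < 9; ++k)
    for (int c = 0; c < C; ++c)
      for (int o = 0; o < Co; ++o) dW(k + 9 * c, o) += acc9(c, k * Co + o);
  arma::Mat<eT> colF;
  im2col_frame<eT>(Xt, rows, H, W, colF);
  arma::Mat<eT> dYf(rows.size(), Co);
  for (std::size_t f = 0; f < rows.size(); ++f)
    for (int o = 0; o < Co; ++o) dYf(f, o) = dYt(rows[f], o);
  dW += colF.t() * dYf;
  if (!need_dx) return;
  // input gradient: nine shifted GEMMs with W transposed; adjoint shift is
  // the flipped kernel, frame rows recomputed exactly
  dX.zeros(NHW, C);
  arma::Mat<eT> Wk9(C, 9 * Co);
  for (int kj = 0; kj < 3; ++kj)
    for (int ki = 0; ki < 3; ++ki)
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Co; ++o)
          Wk9(c, (ki + 3 * kj) * Co + o) = Wm(ki + 3 * kj + 9 * c, o);
  for (int r0 = 0; r0 < NHW; r0 += panel) {
    const int r1 = std::min(NHW, r0 + panel);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int off = (ki - 1) + H * (kj - 1);
        // dx[p] += dY[p - off] * Wk^T (the adjoint shift is reversed)
        const int lo = std::max(r0, off), hi = std::min(r1, NHW - std::max(0, -off));
        if (hi <= lo) continue;
        gemm_blas('N', 'T', hi - lo, C, Co, (eT)1,
                  dYt.memptr() + lo - off, NHW, Wk9.colptr((ki + 3 * kj) * Co),
                  C, (eT)1, dX.memptr() + lo, NHW);
      }
  }
  // frame: dx[p,c] = sum_taps dY[p+off(flip), o] * W[flip, c, o]
  arma::Mat<eT> W2(9 * Co, C);
  for (int kj = 0; kj < 3; ++kj)
    for (int ki = 0; ki < 3; ++ki)
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Co; ++o)
          W2((2 - ki) + 3 * (2 - kj) + 9 * o, c) = Wm(ki + 3 * kj + 9 * c, o);
  arma::Mat<eT> colFd;
  im2col_frame<eT>(dYt, rows, H, W, colFd);
  arma::Mat<eT> dXf = colFd * W2;
  for (std::size_t f = 0; f < rows.size(); ++f)
    for (int c = 0; c < C; ++c) dX(rows[f], c) = dXf(f, c);
}

template <typename eT>
static SEXP conv_fwd_t(const NumericVector& x, const NumericVector& w,
                       const NumericVector& bias, int stride, int pad,
                       bool keep_col) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = out_extent(H, kh, stride, pad), Wo = out_extent(W, kw, stride, pad);
  arma::Mat<eT> Wm;
  load_w<eT>(w, kh * kw * C, Co, Wm);
  NumericVector y = no_init(Ho * Wo * (std::size_t)Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::Mat<eT>* cache = new arma::Mat<eT>();
  arma::Mat<eT> Yt;
  if (conv3_implicit(kh, kw, stride, pad, H, W)) {
    gatherT<eT>(&x[0], H * W, C, N, *cache);  // cache holds Xt
    conv3_fwd_core<eT>(*cache, Wm, H, W, N, Yt);
  } else {
    im2colT<eT>(&x[0], H, W, C, N, kh, kw, stride, pad, *cache);
    Yt = (*cache) * Wm;
  }
  scatterT<eT>(Yt, bias.size() ? &bias[0] : nullptr, Ho * Wo, Co, N, &y[0]);
  if (keep_col) {
    XPtr<arma::Mat<eT>> p(cache, true);
    return List::create(_["y"] = y, _["col"] = p);
  }
  delete cache;
  return y;
}

// [[Rcpp::export]]
SEXP cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector bias,
                  int stride, int pad, bool single, bool keep_col = false) {
  return single ? conv_fwd_t<float>(x, w, bias, stride, pad, keep_col)
                : conv_fwd_t<double>(x, w, bias, stride, pad, keep_col);
}

template <typename eT>
static List conv_bwd_t(const NumericVector& x, const NumericVector& w,
                       const NumericVector& dy, int stride, int pad,
                       bool need_dx, SEXP colcache) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = out_extent(H, kh, stride, pad), Wo = out_extent(W, kw, stride, pad);
  arma::Mat<eT> Wm;
  load_w<eT>(w, kh * kw * C, Co, Wm);
  arma::Mat<eT> dYt;
  gatherT<eT>(&dy[0], Ho * Wo, Co, N, dYt);
  arma::Mat<eT> dW;
  arma::Row<eT> db;
  NumericVector dx(0);
  arma::Mat<eT>* cache;
  bool own = false;
  if (colcache != R_NilValue) {
    XPtr<arma::Mat<eT>> p(colcache);
    cache = p.get();
  } else {
    cache = new arma::Mat<eT>();
    own = true;
    if (conv3_implicit(kh, kw, stride, pad, H, W)) {
      gatherT<eT>(&x[0], H * W, C, N, *cache);
    } else {
      im2colT<eT>(&x[0], H, W, C, N, kh, kw, stride, pad, *cache);
    }
  }
  if (conv3_implicit(kh, kw, stride, pad, H, W)) {
    arma::Mat<eT> dX;
    arma::Col<eT> dbv_;
    conv3_bwd_core<eT>(*cache, Wm, dYt, H, W, N, need_dx, dX, dW, dbv_);
    db = dbv_.t();
    if (need_dx) {
      dx = NumericVector(no_init(x.size()));
      dx.attr("dim") = xd;
      scatterT<eT>(dX, nullptr, H * W, C, N, &dx[0]);
    }
  } else {
    dW = cache->t() * dYt;
    db = arma::sum(dYt, 0);
    if (need_dx) {
      dx = NumericVector(x.size());
      dx.attr("dim") = xd;
      arma::Mat<eT> dcolT = dYt * Wm.t();
      col2imT<eT>(dcolT, H, W, C, N, kh, kw, stride, pad, &dx[0]);
    }
  }
  if (own) delete cache;
  NumericVector dwv(dW.n_elem), dbv(Co);
  for (std::size_t i = 0; i < dW.n_elem; ++i) dwv[i] = (double)dW[i];
  for (int o = 0; o < Co; ++o) dbv[o] = (double)db[o];
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad, bool need_dx, bool single,
                  SEXP colcache = R_NilValue) {
  return single ? conv_bwd_t<float>(x, w, dy, stride, pad, need_dx, colcache)
                : conv_bwd_t<double>(x, w, dy, stride, pad, need_dx, colcache);
}

template <typename eT>
static NumericVector convT_fwd_t(const NumericVector& x, const NumericVector& w,
                                 const NumericVector& bias, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[2];
  const int Ho = (H - 1) * stride + kh, Wo = (W - 1) * stride + kw;
  arma::Mat<eT> Wm;  // (kh*kw*Co) x C, the natural reshape of (kh,kw,Co,C)
  load_w<eT>(w, kh * kw * Co, C, Wm);
  arma::Mat<eT> Xt;
  gatherT<eT>(&x[0], H * W, C, N, Xt);
  arma::Mat<eT> colT = Xt * Wm.t();  // (N*H*W) x (kh*kw*Co)
  NumericVector y(Ho * Wo * (std::size_t)Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  // scatter: input pixel (i,j) adds its kernel patch at (i*s, j*s); this is
  // exactly col2imT with the roles of image and column grid swapped
  col2imT<eT>(colT, Ho, Wo, Co, N, kh, kw, stride, 0, &y[0]);
  if (bias.size()) {
    for (int o = 0; o < Co; ++o) {
      for (int n = 0; n < N; ++n) {
        double* dst = &y[0] + ((std::size_t)n * Co + o) * Ho * Wo;
        for (int p = 0; p < Ho * Wo; ++p) dst[p] += bias[o];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_convT_fwd(NumericVector x, NumericVector w, NumericVector bias,
                            int stride, bool single) {
  return single ? convT_fwd_t<float>(x, w, bias, stride)
                : convT_fwd_t<double>(x, w, bias, stride);
}

template <typename eT>
static List convT_bwd_t(const NumericVector& x, const NumericVector& w,
                        const NumericVector& dy, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[2];
  const int Ho = (H - 1) * stride + kh, Wo = (W - 1) * stride + kw;
  arma::Mat<eT> Wm;
  load_w<eT>(w, kh * kw * Co, C, Wm);
  arma::Mat<eT> dcolT;
  im2colT<eT>(&dy[0], Ho, Wo, Co, N, kh, kw, stride, 0, dcolT);
  arma::Mat<eT> Xt;
  gatherT<eT>(&x[0], H * W, C, N, Xt);
  arma::Mat<eT> dXt = dcolT * Wm;  // (N*H*W) x C
  arma::Mat<eT> dW = dcolT.t() * Xt;
  NumericVector dx = no_init(x.size());
  dx.attr("dim") = xd;
  scatterT<eT>(dXt, nullptr, H * W, C, N, &dx[0]);
  NumericVector dwv(dW.n_elem), dbv(Co);
  for (std::size_t i = 0; i < dW.n_elem; ++i) dwv[i] = (double)dW[i];
  for (int o = 0; o < Co; ++o) {
    double s = 0;
    for (int n = 0; n < N; ++n) {
      const double* src = &dy[0] + ((std::size_t)n * Co + o) * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p) s += src[p];
    }
    dbv[o] = s;
  }
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_convT_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, bool single) {
  return single ? convT_bwd_t<float>(x, w, dy, stride)
                : convT_bwd_t<double>(x, w, dy, stride);
}

// Bilinear x2 upsampling (half-pixel centres, edges clamped) and its adjoint.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * (std::size_t)C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wi(Ho);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[o] = (int)std::floor(s);
    i1[o] = std::min(i0[o] + 1, H - 1);
    wi[o] = s - i0[o];
  }
  for (std::size_t cn = 0; cn < (std::size_t)C * N; ++cn) {
    const double* xc = &x[0] + cn * H * W;
    double* yc = &y[0] + cn * Ho * Wo;
    for (int oj = 0; oj < Wo; ++oj) {
      const int j0 = i0[oj] < W ? 0 : 0;  // reuse row tables for columns below
      (void)j0;
      double t = (oj + 0.5) / 2.0 - 0.5;
      if (t < 0) t = 0;
      if (t > W - 1) t = W - 1;
      const int c0 = (int)std::floor(t), c1 = std::min(c0 + 1, W - 1);
      const double wj = t - c0;
      for (int oi = 0; oi < Ho; ++oi) {
        const double a = xc[i0[oi] + (std::size_t)c0 * H], b = xc[i1[oi] + (std::size_t)c0 * H];
        const double c = xc[i0[oi] + (std::size_t)c1 * H], d = xc[i1[oi] + (std::size_t)c1 * H];
        yc[oi + (std::size_t)oj * Ho] =
            (1 - wj) * ((1 - wi[oi]) * a + wi[oi] * b) + wj * ((1 - wi[oi]) * c + wi[oi] * d);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(H * W * (std::size_t)C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (std::size_t cn = 0; cn < (std::size_t)C * N; ++cn) {
    const double* dyc = &dy[0] + cn * Ho * Wo;
    double* dxc = &dx[0] + cn * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      double t = (oj + 0.5) / 2.0 - 0.5;
      if (t < 0) t = 0;
      if (t > W - 1) t = W - 1;
      const int c0 = (int)std::floor(t), c1 = std::min(c0 + 1, W - 1);
      const double wj = t - c0;
      for (int oi = 0; oi < Ho; ++oi) {
        double s = (oi + 0.5) / 2.0 - 0.5;
        if (s < 0) s = 0;
        if (s > H - 1) s = H - 1;
        const int r0 = (int)std::floor(s), r1 = std::min(r0 + 1, H - 1);
        const double wi = s - r0;
        const double g = dyc[oi + (std::size_t)oj * Ho];
        dxc[r0 + (std::size_t)c0 * H] += (1 - wj) * (1 - wi) * g;
        dxc[r1 + (std::size_t)c0 * H] += (1 - wj) * wi * g;
        dxc[r0 + (std::size_t)c1 * H] += wj * (1 - wi) * g;
        dxc[r1 + (std::size_t)c1 * H] += wj * wi * g;
      }
    }
  }
  return dx;
}

// Inverse-mapped affine warp of a single-channel image.  m is the 2x3 matrix
// sending output (row, col) pixel centres to source coordinates; bilinear or
// nearest-neighbour sampling, constant fill outside the support.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp(NumericMatrix img, NumericVector m,
                              bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double si = m[0] * i + m[1] * j + m[2];
      const double sj = m[3] * i + m[4] * j + m[5];
      if (bilinear) {
        const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        if (i0 < -1 || i0 > H - 1 || j0 < -1 || j0 > W - 1) {
          out(i, j) = fill;
          continue;
        }
        const double wi = si - i0, wj = sj - j0;
        auto at = [&](int a, int b) {
          return (a < 0 || a >= H || b < 0 || b >= W) ? fill : img(a, b);
        };
        out(i, j) = (1 - wj) * ((1 - wi) * at(i0, j0) + wi * at(i0 + 1, j0)) +
                    wj * ((1 - wi) * at(i0, j0 + 1) + wi * at(i0 + 1, j0 + 1));
      } else {
        const int ri = (int)std::lround(si), rj = (int)std::lround(sj);
        out(i, j) = (ri < 0 || ri >= H || rj < 0 || rj >= W) ? fill : img(ri, rj);
      }
    }
  }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// of the complement of a seed set, with anisotropic pixel spacing.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double sden = 2.0 * s2 * (q - v[k]);
    double s = (f[q] + s2 * q * q - f[v[k]] - s2 * v[k] * v[k]) / sden;
    while (s <= z[k]) {
      --k;
      sden = 2.0 * s2 * (q - v[k]);
      s = (f[q] + s2 * q * q - f[v[k]] - s2 * v[k] * v[k]) / sden;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix seed, double sy, double sx) {
  const int H = seed.nrow(), W = seed.ncol();
  NumericMatrix d(H, W);
  const double INF = 1e30;
  std::vector<double> f(std::max(H, W)), g(std::max(H, W));
  // columns first
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = seed(i, j) ? 0.0 : INF;
    f.resize(H);
    g.resize(H);
    edt_1d(f, g, sy);
    for (int i = 0; i < H; ++i) d(i, j) = g[i];
    f.resize(std::max(H, W));
    g.resize(std::max(H, W));
  }
  // then rows
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d(i, j);
    f.resize(W);
    g.resize(W);
    edt_1d(f, g, sx);
    for (int j = 0; j < W; ++j) d(i, j) = g[j];
    f.resize(std::max(H, W));
    g.resize(std::max(H, W));
  }
  return d;
}

// ---- per-channel reductions for batch normalization ----
// x has layout (H, W, C, N); statistics pool over H, W and N per channel.

// [[Rcpp::export]]
List cpp_chan_moments(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = &x[0] + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) {
        s += p[i];
        s2 += p[i] * p[i];
      }
    }
    const double m = (double)HW * N;
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y = no_init(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const double* p = &x[0] + HW * (c + (std::size_t)C * n);
      double* q = &y[0] + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) q[i] = ac * p[i] + bc;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_chan_dot(NumericVector x, NumericVector y) {
  IntegerVector xd = x.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    double s = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = &x[0] + HW * (c + (std::size_t)C * n);
      const double* q = &y[0] + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) s += p[i] * q[i];
    }
    out[c] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chan_sum(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    double s = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = &x[0] + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) s += p[i];
    }
    out[c] = s;
  }
  return out;
}

// dx = a[c]*dy + b[c] + c[c]*xhat, the closed form of the batch-norm input
// gradient once the three per-channel coefficients are known.
// [[Rcpp::export]]
NumericVector cpp_bn_dx(NumericVector dy, NumericVector xhat, NumericVector a,
                        NumericVector b, NumericVector cc) {
  IntegerVector xd = dy.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out = no_init(dy.size());
  out.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], gc = cc[c];
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double* p = &dy[0] + off;
      const double* h = &xhat[0] + off;
      double* q = &out[0] + off;
      for (std::size_t i = 0; i < HW; ++i) q[i] = ac * p[i] + bc + gc * h[i];
    }
  return out;
}

// ---- fused elementwise / reshaping helpers (hot path during training) ----

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = no_init(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx = no_init(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_fwd(NumericVector x) {
  NumericVector y = no_init(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx = no_init(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = dy[i] * y[i] * (1.0 - y[i]);
  return dx;
}

// concatenate two (h,w,c,b) arrays along the channel axis
// [[Rcpp::export]]
NumericVector cpp_concat2(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  const std::size_t HW = (std::size_t)da[0] * da[1];
  const int Ca = da[2], Cb = db[2], N = da[3];
  NumericVector y = no_init(HW * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(da[0], da[1], Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(&a[0] + HW * Ca * n, &a[0] + HW * Ca * (n + 1),
              &y[0] + HW * (Ca + Cb) * n);
    std::copy(&b[0] + HW * Cb * n, &b[0] + HW * Cb * (n + 1),
              &y[0] + HW * (Ca + Cb) * n + HW * Ca);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_split2(NumericVector dy, int Ca) {
  IntegerVector d = dy.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3], Cb = C - Ca;
  NumericVector a = no_init(HW * Ca * N), b = no_init(HW * Cb * N);
  a.attr("dim") = IntegerVector::create(d[0], d[1], Ca, N);
  b.attr("dim") = IntegerVector::create(d[0], d[1], Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(&dy[0] + HW * C * n, &dy[0] + HW * C * n + HW * Ca,
              &a[0] + HW * Ca * n);
    std::copy(&dy[0] + HW * C * n + HW * Ca, &dy[0] + HW * C * (n + 1),
              &b[0] + HW * Cb * n);
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// x * att with att (1,1,C,N)
// [[Rcpp::export]]
NumericVector cpp_scale_channel_fwd(NumericVector x, NumericVector att) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y = no_init(x.size());
  y.attr("dim") = d;
  for (int cn = 0; cn < C * N; ++cn) {
    const double a = att[cn];
    const double* p = &x[0] + HW * cn;
    double* q = &y[0] + HW * cn;
    for (std::size_t i = 0; i < HW; ++i) q[i] = p[i] * a;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_scale_channel_bwd(NumericVector dy, NumericVector x, NumericVector att) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector dx = no_init(x.size()), datt = no_init(C * N);
  dx.attr("dim") = d;
  datt.attr("dim") = IntegerVector::create(1, 1, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double a = att[cn];
    const double* g = &dy[0] + HW * cn;
    const double* p = &x[0] + HW * cn;
    double* q = &dx[0] + HW * cn;
    double s = 0;
    for (std::size_t i = 0; i < HW; ++i) {
      q[i] = g[i] * a;
      s += g[i] * p[i];
    }
    datt[cn] = s;
  }
  return List::create(_["dx"] = dx, _["datt"] = datt);
}

// x * att with att (H,W,1,N)
// [[Rcpp::export]]
NumericVector cpp_scale_spatial_fwd(NumericVector x, NumericVector att) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y = no_init(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* a = &att[0] + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* p = &x[0] + HW * (c + (std::size_t)C * n);
      double* q = &y[0] + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) q[i] = p[i] * a[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_scale_spatial_bwd(NumericVector dy, NumericVector x, NumericVector att) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector dx(x.size()), datt(HW * N);
  dx.attr("dim") = d;
  datt.attr("dim") = IntegerVector::create(d[0], d[1], 1, N);
  for (int n = 0; n < N; ++n) {
    const double* a = &att[0] + HW * n;
    double* da = &datt[0] + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* g = &dy[0] + HW * (c + (std::size_t)C * n);
      const double* p = &x[0] + HW * (c + (std::size_t)C * n);
      double* q = &dx[0] + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) {
        q[i] = g[i] * a[i];
        da[i] += g[i] * p[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["datt"] = datt);
}

// per-pixel max over channels -> (H,W,1,N)
// [[Rcpp::export]]
NumericVector cpp_cmax_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y = no_init(HW * N);
  y.attr("dim") = IntegerVector::create(d[0], d[1], 1, N);
  for (int n = 0; n < N; ++n) {
    double* q = &y[0] + HW * n;
    const double* p0 = &x[0] + HW * (std::size_t)C * n;
    for (std::size_t i = 0; i < HW; ++i) q[i] = p0[i];
    for (int c = 1; c < C; ++c) {
      const double* p = p0 + HW * c;
      for (std::size_t i = 0; i < HW; ++i)
        if (p[i] > q[i]) q[i] = p[i];
    }
  }
  return y;
}

// gradient of the channel max: maxima share the gradient equally on ties
// [[Rcpp::export]]
NumericVector cpp_cmax_bwd(NumericVector dy, NumericVector x, NumericVector y) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector dx = no_init(x.size());
  dx.attr("dim") = d;
  std::vector<int> cnt(HW);
  for (int n = 0; n < N; ++n) {
    const double* ym = &y[0] + HW * n;
    const double* g = &dy[0] + HW * n;
    std::fill(cnt.begin(), cnt.end(), 0);
    const double* p0 = &x[0] + HW * (std::size_t)C * n;
    for (int c = 0; c < C; ++c) {
      const double* p = p0 + HW * c;
      for (std::size_t i = 0; i < HW; ++i)
        if (p[i] == ym[i]) ++cnt[i];
    }
    for (int c = 0; c < C; ++c) {
      const double* p = p0 + HW * c;
      double* q = &dx[0] + HW * ((std::size_t)C * n + c);
      for (std::size_t i = 0; i < HW; ++i)
        q[i] = (p[i] == ym[i]) ? g[i] / cnt[i] : 0.0;
    }
  }
  return dx;
}

// per-pixel mean over channels -> (H,W,1,N)
// [[Rcpp::export]]
NumericVector cpp_cmean_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y = no_init(HW * N);
  y.attr("dim") = IntegerVector::create(d[0], d[1], 1, N);
  for (int n = 0; n < N; ++n) {
    double* q = &y[0] + HW * n;
    const double* p0 = &x[0] + HW * (std::size_t)C * n;
    for (std::size_t i = 0; i < HW; ++i) q[i] = p0[i];
    for (int c = 1; c < C; ++c) {
      const double* p = p0 + HW * c;
      for (std::size_t i = 0; i < HW; ++i) q[i] += p[i];
    }
    for (std::size_t i = 0; i < HW; ++i) q[i] /= C;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_cmean_bwd(NumericVector dy, int C) {
  IntegerVector d = dy.attr("dim");
  const std::size_t HW = (std::size_t)d[0] * d[1];
  const int N = d[3];
  NumericVector dx = no_init(HW * (std::size_t)C * N);
  dx.attr("dim") = IntegerVector::create(d[0], d[1], C, N);
  for (int n = 0; n < N; ++n) {
    const double* g = &dy[0] + HW * n;
    for (int c = 0; c < C; ++c) {
      double* q = &dx[0] + HW * ((std::size_t)C * n + c);
      for (std::size_t i = 0; i < HW; ++i) q[i] = g[i] / C;
    }
  }
  return dx;
}

// Pin the BLAS thread count (OpenBLAS) when the symbol is available; the
// training loop is sized for deterministic single-threaded execution.
#include <dlfcn.h>
// [[Rcpp::export]]
bool cpp_set_blas_threads(int n) {
  typedef void (*setter)(int);
  setter f = (setter)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f == nullptr) return false;
  f(n);
  return true;
}
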