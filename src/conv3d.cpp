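// im2col / col2im kernels for 3D convolutions on channel-last arrays.
//
// Feature maps are R arrays with dim = c(D, H, W, C) (column-major, so the
// first spatial axis varies fastest).  im2col unrolls every receptive field
// into one ROW of an (N_out x k^3*C) matrix so that a convolution becomes a
// single GEMM `cols %*% weight_matrix` on the R side; col2im is its adjoint
// (scatter-add), used for input gradients and transposed convolutions.  The
// row-major-in-N layout makes both the C++ writes and the GEMM operands
// stride-1 in memory.
//
// Column ordering of the patch matrix: kd fastest, then kh, kw, then input
// channel — matching matrix(weights, nrow = k^3 * C) of a weight array with
// dim = c(k, k, k, C, C_out).  Row ordering: od fastest, then oh, ow.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims,
                       int k, int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int oD = out_len(D, k, stride, pad);
  const int oH = out_len(H, k, stride, pad);
  const int oW = out_len(W, k, stride, pad);
  const R_xlen_t N = (R_xlen_t)oD * oH * oW;
  NumericMatrix cols(N, (R_xlen_t)k * k * k * C);
  const double *px = x.begin();
  double *pc = cols.begin();

  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const int col = kd + k * (kh + k * (kw + k * c));
          double *dst = pc + (R_xlen_t)col * N;
          for (int ow = 0; ow < oW; ++ow) {
            const int w = ow * stride - pad + kw;
            for (int oh = 0; oh < oH; ++oh) {
              const int h = oh * stride - pad + kh;
              R_xlen_t n = (R_xlen_t)oD * (oh + (R_xlen_t)oH * ow);
              if (w < 0 || w >= W || h < 0 || h >= H) {
                for (int od = 0; od < oD; ++od) dst[n + od] = 0.0;
                continue;
              }
              const double *src = xc + (R_xlen_t)D * (h + (R_xlen_t)H * w);
              for (int od = 0; od < oD; ++od) {
                const int d = od * stride - pad + kd;
                dst[n + od] = (d >= 0 && d < D) ? src[d] : 0.0;
              }
            }
          }
        }
  }
  return cols;
}

// Adjoint of im2col3d: scatter-add the (N x k^3*C) patch matrix back into
// an array of dims c(D, H, W, C) for the same (k, stride, pad).
// [[Rcpp::export(name = ".col2im3d")]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector dims,
                       int k, int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int oD = out_len(D, k, stride, pad);
  const int oH = out_len(H, k, stride, pad);
  const int oW = out_len(W, k, stride, pad);
  const R_xlen_t N = (R_xlen_t)oD * oH * oW;
  NumericVector x((R_xlen_t)D * H * W * C);
  x.attr("dim") = dims;
  const double *pc = cols.begin();
  double *px = x.begin();

  for (int c = 0; c < C; ++c) {
    double *xc = px + (R_xlen_t)c * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const int col = kd + k * (kh + k * (kw + k * c));
          const double *src0 = pc + (R_xlen_t)col * N;
          for (int ow = 0; ow < oW; ++ow) {
            const int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int oh = 0; oh < oH; ++oh) {
              const int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const double *src = src0 + (R_xlen_t)oD * (oh + (R_xlen_t)oH * ow);
              double *dst = xc + (R_xlen_t)D * (h + (R_xlen_t)H * w);
              for (int od = 0; od < oD; ++od) {
                const int d = od * stride - pad + kd;
                if (d >= 0 && d < D) dst[d] += src[od];
              }
            }
          }
        }
  }
  return x;
}

// 2x2x2 max pooling with stride 2.  Returns the pooled array and the
// flat (1-based) indices of the winning voxels for the backward pass.
// [[Rcpp::export(name = ".maxpool3d2")]]
List maxpool3d2(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int oD = D / 2, oH = H / 2, oW = W / 2;
  NumericVector y((R_xlen_t)oD * oH * oW * C);
  IntegerVector arg((R_xlen_t)oD * oH * oW * C);
  y.attr("dim") = IntegerVector::create(oD, oH, oW, C);
  const double *px = x.begin();
  R_xlen_t n = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = (R_xlen_t)c * D * H * W;
    for (int ow = 0; ow < oW; ++ow)
      for (int oh = 0; oh < oH; ++oh)
        for (int od = 0; od < oD; ++od) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                R_xlen_t i = coff + (2 * od + dd)
                  + (R_xlen_t)D * ((2 * oh + dh) + (R_xlen_t)H * (2 * ow + dw));
                if (px[i] > best) { best = px[i]; besti = i; }
              }
          y[n] = best;
          arg[n] = (int)(besti + 1);
          ++n;
        }
  }
  return List::create(_["values"] = y, _["argmax"] = arg);
}
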