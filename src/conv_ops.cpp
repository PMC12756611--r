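// Patch-extraction kernels for BLAS-based 2-D convolution.
//
// Tensors are R numeric arrays in (B, C, H, W) order, column-major, so the
// batch index varies fastest.  im2col lays patches out as a
// (C*kh*kw) x (B*Ho*Wo) matrix whose column index is b + B*(ho + Ho*wo) and
// whose row index is c + C*(i + kh*j); the conv weight array (Cout, Cin, kh, kw)
// then flattens directly to the (Cout) x (Cin*kh*kw) left factor of a single
// GEMM per layer.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int B, int C, int H, int W,
                         int kh, int kw, int ph, int pw, int sh, int sw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t K = (R_xlen_t)C * kh * kw;
  NumericMatrix out(K, (R_xlen_t)B * Ho * Wo);
  const double *px = x.begin();
  double *po = out.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int b = 0; b < B; ++b) {
        double *col = po + K * ((R_xlen_t)b + (R_xlen_t)B * (ho + (R_xlen_t)Ho * wo));
        for (int j = 0; j < kw; ++j) {
          const int w = wo * sw - pw + j;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * sh - ph + i;
            double *dst = col + (R_xlen_t)C * (i + kh * j);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double *src = px + (R_xlen_t)b +
                (R_xlen_t)B * (R_xlen_t)C * (h + (R_xlen_t)H * w);
              for (int c = 0; c < C; ++c) dst[c] = src[(R_xlen_t)B * c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns back into a (B, C, H, W) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int B, int C, int H, int W,
                         int kh, int kw, int ph, int pw, int sh, int sw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t K = (R_xlen_t)C * kh * kw;
  NumericVector out((R_xlen_t)B * C * H * W);
  double *po = out.begin();
  const double *pc = cols.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int b = 0; b < B; ++b) {
        const double *col = pc + K * ((R_xlen_t)b + (R_xlen_t)B * (ho + (R_xlen_t)Ho * wo));
        for (int j = 0; j < kw; ++j) {
          const int w = wo * sw - pw + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * sh - ph + i;
            if (h < 0 || h >= H) continue;
            const double *src = col + (R_xlen_t)C * (i + kh * j);
            double *dst = po + (R_xlen_t)b +
              (R_xlen_t)B * (R_xlen_t)C * (h + (R_xlen_t)H * w);
            for (int c = 0; c < C; ++c) dst[(R_xlen_t)B * c] += src[c];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(B, C, H, W);
  return out;
}

// 2x2 max pooling, stride 2 (floor semantics).  Returns the pooled array and
// the 1-based linear argmax indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int B, int C, int H, int W) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)B * C * Ho * Wo);
  NumericVector arg((R_xlen_t)B * C * Ho * Wo);
  const double *px = x.begin();
  double *py = y.begin(), *pa = arg.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int h = 2 * ho + di, w = 2 * wo + dj;
              const R_xlen_t idx = (R_xlen_t)b +
                (R_xlen_t)B * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
              if (px[idx] > best) { best = px[idx]; besti = idx; }
            }
          }
          const R_xlen_t o = (R_xlen_t)b +
            (R_xlen_t)B * (c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo));
          py[o] = best;
          pa[o] = (double)(besti + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, NumericVector argmax,
                                    int B, int C, int H, int W) {
  NumericVector dx((R_xlen_t)B * C * H * W);
  double *pdx = dx.begin();
  const double *pdy = dy.begin(), *pa = argmax.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) pdx[(R_xlen_t)pa[k] - 1] += pdy[k];
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return dx;
}
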