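#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensors are stored as R arrays with dim (N, H, W, C), column-major, so the
// sample index varies fastest.  im2col lays out one row per (n, h, w) output
// position -- also with n fastest -- and one column per kernel tap
// (kh fastest, then kw, then input channel), so that a conv forward pass is a
// single GEMM against a (kh*kw*C x F) weight matrix and the (N*H*W x F)
// result reshapes directly to (N, H, W, F).  "Same" zero padding, stride 1.

// [[Rcpp::export]]
NumericMatrix im2col_nhwc(NumericVector x, int N, int H, int W, int C,
                          int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  const R_xlen_t rows = (R_xlen_t)N * H * W;
  NumericMatrix P(rows, kh * kw * C);
  const double* px = REAL(x);
  double* pp = REAL(P);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* pcol = pp + (R_xlen_t)col * rows;
        for (int w = 0; w < W; ++w) {
          const int ww = w + kj - pw;
          if (ww < 0 || ww >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hh = h + ki - ph;
            if (hh < 0 || hh >= H) continue;
            const double* src = px + (R_xlen_t)N * (hh + H * (ww + (R_xlen_t)W * c));
            double* dst = pcol + (R_xlen_t)N * (h + H * (R_xlen_t)w);
            std::memcpy(dst, src, sizeof(double) * N);
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix P, int N, int H, int W, int C,
                          int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  const R_xlen_t rows = (R_xlen_t)N * H * W;
  NumericVector gx((R_xlen_t)N * H * W * C);
  double* pgx = REAL(gx);
  const double* pp = REAL(P);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* pcol = pp + (R_xlen_t)col * rows;
        for (int w = 0; w < W; ++w) {
          const int ww = w + kj - pw;
          if (ww < 0 || ww >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hh = h + ki - ph;
            if (hh < 0 || hh >= H) continue;
            double* dst = pgx + (R_xlen_t)N * (hh + H * (ww + (R_xlen_t)W * c));
            const double* src = pcol + (R_xlen_t)N * (h + H * (R_xlen_t)w);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }
  return gx;
}

// Non-overlapping max pooling over (ph x pw) windows.  Returns the pooled
// tensor and the 1-based linear index of each argmax (ties to the first
// position scanned), which the backward pass uses as a scatter target.
// [[Rcpp::export]]
List maxpool_nhwc(NumericVector x, int N, int H, int W, int C,
                  int ph, int pw) {
  const int Ho = H / ph, Wo = W / pw;
  NumericVector y((R_xlen_t)N * Ho * Wo * C);
  IntegerVector idx(y.size());
  const double* px = REAL(x);
  double* py = REAL(y);
  int* pidx = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t best_i = 0;
          for (int dj = 0; dj < pw; ++dj) {
            const int w = wo * pw + dj;
            for (int di = 0; di < ph; ++di) {
              const int h = ho * ph + di;
              const R_xlen_t i =
                n + (R_xlen_t)N * (h + H * (w + (R_xlen_t)W * c));
              if (px[i] > best) { best = px[i]; best_i = i; }
            }
          }
          const R_xlen_t o =
            n + (R_xlen_t)N * (ho + Ho * (wo + (R_xlen_t)Wo * c));
          py[o] = best;
          pidx[o] = (int)(best_i + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Per-sample histogram of integer intensities in 0..(nbins-1); rows sum to 1.
// Feeds the embedding branch (intensity-vocabulary average pooling).
// [[Rcpp::export]]
NumericMatrix intensity_counts(IntegerVector x, int N, int P, int nbins) {
  NumericMatrix out(N, nbins);
  const int* px = INTEGER(x);
  double* po = REAL(out);
  for (R_xlen_t j = 0; j < (R_xlen_t)P; ++j) {
    const int* col = px + j * N;
    for (int n = 0; n < N; ++n) {
      int v = col[n];
      if (v < 0) v = 0;
      if (v >= nbins) v = nbins - 1;
      po[n + (R_xlen_t)N * v] += 1.0;
    }
  }
  const double inv = 1.0 / (double)P;
  for (R_xlen_t i = 0; i < (R_xlen_t)N * nbins; ++i) po[i] *= inv;
  return out;
}
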