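// 3D convolution / pooling / upsampling primitives for the segmentation
// backend. Feature maps are (C x N) matrices: one column per voxel in R's
// column-major order of the spatial dims (d0 fastest). 3x3x3 convolutions
// use zero padding of 1 and are evaluated as im2col + GEMM so the heavy
// lifting lands in BLAS. Weight layout: W is (C_out x 27*C_in) with column
// blocks ordered offset-major (dz slowest, dx fastest), channels within.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col3(const mat& x, int d0, int d1, int d2) {
  const uword C = x.n_rows;
  const uword N = x.n_cols;
  mat out(C * 27, N, fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const uword r0 = (uword)o * C;
        int i0 = std::max(0, -dx), i1 = std::min(d0 - 1, d0 - 1 - dx);
        if (i0 > i1) continue;
        const uword len = (uword)(i1 - i0 + 1);
        for (int k = std::max(0, -dz); k <= std::min(d2 - 1, d2 - 1 - dz); ++k)
          for (int j = std::max(0, -dy); j <= std::min(d1 - 1, d1 - 1 - dy); ++j) {
            uword dest = (uword)i0 + (uword)d0 * ((uword)j + (uword)d1 * (uword)k);
            uword src = (uword)(i0 + dx) +
                        (uword)d0 * ((uword)(j + dy) + (uword)d1 * (uword)(k + dz));
            out.submat(r0, dest, r0 + C - 1, dest + len - 1) = x.cols(src, src + len - 1);
          }
      }
  return out;
}

static mat col2im3(const mat& g, uword C, int d0, int d1, int d2) {
  mat out(C, g.n_cols, fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const uword r0 = (uword)o * C;
        int i0 = std::max(0, -dx), i1 = std::min(d0 - 1, d0 - 1 - dx);
        if (i0 > i1) continue;
        const uword len = (uword)(i1 - i0 + 1);
        for (int k = std::max(0, -dz); k <= std::min(d2 - 1, d2 - 1 - dz); ++k)
          for (int j = std::max(0, -dy); j <= std::min(d1 - 1, d1 - 1 - dy); ++j) {
            uword dest = (uword)i0 + (uword)d0 * ((uword)j + (uword)d1 * (uword)k);
            uword src = (uword)(i0 + dx) +
                        (uword)d0 * ((uword)(j + dy) + (uword)d1 * (uword)(k + dz));
            out.cols(src, src + len - 1) +=
                g.submat(r0, dest, r0 + C - 1, dest + len - 1);
          }
      }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const arma::mat& W, const arma::vec& b,
                        Rcpp::IntegerVector dim) {
  mat cols = im2col3(x, dim[0], dim[1], dim[2]);
  mat out = W * cols;
  out.each_col() += b;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::mat& x, const arma::mat& W, const arma::mat& gout,
                         Rcpp::IntegerVector dim) {
  mat cols = im2col3(x, dim[0], dim[1], dim[2]);
  mat gW = gout * cols.t();
  cols.reset();
  vec gb = sum(gout, 1);
  mat tmp = W.t() * gout;
  mat gx = col2im3(tmp, x.n_rows, dim[0], dim[1], dim[2]);
  return Rcpp::List::create(Rcpp::Named("gW") = gW, Rcpp::Named("gb") = gb,
                            Rcpp::Named("gx") = gx);
}

// 2x max pooling; dims must be even. Returns pooled map and the 1-based
// source column index of each max (per channel) for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2(const arma::mat& x, Rcpp::IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const int o0 = d0 / 2, o1 = d1 / 2, o2 = d2 / 2;
  const uword C = x.n_rows;
  mat out(C, (uword)o0 * o1 * o2);
  umat idx(C, out.n_cols);
  uword n = 0;
  for (int k = 0; k < o2; ++k)
    for (int j = 0; j < o1; ++j)
      for (int i = 0; i < o0; ++i, ++n) {
        for (uword c = 0; c < C; ++c) {
          double best = -datum::inf;
          uword besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                uword src = (uword)(2 * i + dx) +
                            (uword)d0 * ((uword)(2 * j + dy) + (uword)d1 * (uword)(2 * k + dz));
                if (x(c, src) > best) {
                  best = x(c, src);
                  besti = src;
                }
              }
          out(c, n) = best;
          idx(c, n) = besti + 1;
        }
      }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::umat& idx, const arma::mat& gout, int n_in) {
  mat gx(gout.n_rows, (uword)n_in, fill::zeros);
  for (uword n = 0; n < gout.n_cols; ++n)
    for (uword c = 0; c < gout.n_rows; ++c)
      gx(c, idx(c, n) - 1) += gout(c, n);
  return gx;
}

// Nearest-neighbor 2x upsampling; dim is the (small) input grid.
// [[Rcpp::export]]
arma::mat cpp_upsample2(const arma::mat& x, Rcpp::IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  mat out(x.n_rows, (uword)(2 * d0) * (2 * d1) * (2 * d2));
  uword n = 0;
  for (int k = 0; k < 2 * d2; ++k)
    for (int j = 0; j < 2 * d1; ++j)
      for (int i = 0; i < 2 * d0; ++i, ++n) {
        uword src = (uword)(i / 2) + (uword)d0 * ((uword)(j / 2) + (uword)d1 * (uword)(k / 2));
        out.col(n) = x.col(src);
      }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_upsample2_bwd(const arma::mat& gout, Rcpp::IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  mat gx(gout.n_rows, (uword)d0 * d1 * d2, fill::zeros);
  uword n = 0;
  for (int k = 0; k < 2 * d2; ++k)
    for (int j = 0; j < 2 * d1; ++j)
      for (int i = 0; i < 2 * d0; ++i, ++n) {
        uword src = (uword)(i / 2) + (uword)d0 * ((uword)(j / 2) + (uword)d1 * (uword)(k / 2));
        gx.col(src) += gout.col(n);
      }
  return gx;
}
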