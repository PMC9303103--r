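// 2-D convolution primitives for the segmentation network.
// Layout: activations are H x W x C arma::cubes (column-major, matching R
// arrays); weights are Cout x (Cin*k*k) matrices with column-within-patch
// order (channel, kernel-col, kernel-row), i.e. index c*k*k + kj*k + ki.
//
// The patch matrix is kept transposed, P x (Cin*k*k) with P = Ho*Wo, so
// patch extraction writes contiguous column segments and the GEMM output
// (P x Cout) is laid out exactly like the output cube's slices. For 1x1
// unpadded stride-1 convolutions the patch matrix is an alias of the input
// cube's memory (no copy). Backward recomputes the patch matrix rather
// than caching it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void out_size(int H, int W, int k, int stride, int dilation, int pad,
                     int &Ho, int &Wo) {
  const int eff = dilation * (k - 1) + 1;
  Ho = (H + 2 * pad - eff) / stride + 1;
  Wo = (W + 2 * pad - eff) / stride + 1;
  if (Ho < 1 || Wo < 1)
    Rcpp::stop("convolution output would be empty (input %dx%d, kernel %d)",
               H, W, k);
}

// colsT: (Ho*Wo) x (Cin*k*k)
static void im2col_t(const cube &x, int k, int stride, int dilation, int pad,
                     mat &colsT, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  colsT.zeros(Ho * Wo, Cin * k * k);
  for (int c = 0; c < Cin; ++c) {
    const double *src = x.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double *dst = colsT.colptr(c * k * k + kj * k + ki);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pad + kj * dilation;
          if (ij < 0 || ij >= W) continue;
          const double *col = src + (size_t)ij * H;
          double *d = dst + (size_t)oj * Ho;
          // valid oi range: 0 <= oi*stride - pad + ki*dilation < H
          int lo = 0, off = ki * dilation - pad;
          while (lo * stride + off < 0) ++lo;
          int hi = Ho - 1;
          while (hi >= lo && hi * stride + off >= H) --hi;
          if (stride == 1) {
            for (int oi = lo; oi <= hi; ++oi) d[oi] = col[oi + off];
          } else {
            for (int oi = lo; oi <= hi; ++oi) d[oi] = col[oi * stride + off];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube &x, const arma::mat &w,
                     const arma::vec &b, int k, int stride, int dilation,
                     int pad) {
  int Ho, Wo;
  out_size(x.n_rows, x.n_cols, k, stride, dilation, pad, Ho, Wo);
  if ((int)w.n_cols != (int)x.n_slices * k * k)
    Rcpp::stop("weight/input channel mismatch");
  const int Cout = w.n_rows;
  cube out(Ho, Wo, Cout);
  mat y(out.memptr(), (size_t)Ho * Wo, Cout, false, true);
  if (k == 1 && stride == 1 && pad == 0) {
    const mat xin(const_cast<double *>(x.memptr()), (size_t)Ho * Wo,
                  x.n_slices, false, true);
    y = xin * w.t();
  } else {
    mat colsT;
    im2col_t(x, k, stride, dilation, pad, colsT, Ho, Wo);
    y = colsT * w.t();
  }
  y.each_row() += b.t();
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube &x, const arma::mat &w,
                     const arma::cube &gy, int k, int stride, int dilation,
                     int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  int Ho2, Wo2;
  out_size(H, W, k, stride, dilation, pad, Ho2, Wo2);
  if (Ho != Ho2 || Wo != Wo2 || (int)w.n_rows != Cout)
    Rcpp::stop("gradient shape inconsistent with convolution geometry");

  const mat gyT(const_cast<double *>(gy.memptr()), (size_t)Ho * Wo, Cout,
                false, true);
  vec gb = sum(gyT, 0).t();
  cube gx(H, W, Cin, fill::zeros);
  mat gw;

  if (k == 1 && stride == 1 && pad == 0) {
    const mat xin(const_cast<double *>(x.memptr()), (size_t)H * W, Cin,
                  false, true);
    gw = gyT.t() * xin;
    mat gxm(gx.memptr(), (size_t)H * W, Cin, false, true);
    gxm = gyT * w;
    return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                              Rcpp::Named("gb") = gb);
  }

  mat colsT;
  im2col_t(x, k, stride, dilation, pad, colsT, Ho, Wo);
  gw = gyT.t() * colsT;
  mat gcolsT = gyT * w; // P x (Cin*k*k)

  // col2im: scatter-add the patch gradients back (reverse of im2col_t)
  for (int c = 0; c < Cin; ++c) {
    double *dst = gx.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double *src = gcolsT.colptr(c * k * k + kj * k + ki);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pad + kj * dilation;
          if (ij < 0 || ij >= W) continue;
          double *col = dst + (size_t)ij * H;
          const double *s = src + (size_t)oj * Ho;
          int lo = 0, off = ki * dilation - pad;
          while (lo * stride + off < 0) ++lo;
          int hi = Ho - 1;
          while (hi >= lo && hi * stride + off >= H) --hi;
          if (stride == 1) {
            for (int oi = lo; oi <= hi; ++oi) col[oi + off] += s[oi];
          } else {
            for (int oi = lo; oi <= hi; ++oi) col[oi * stride + off] += s[oi];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
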