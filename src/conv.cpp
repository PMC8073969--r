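// Convolution primitives for the slice-reconstruction networks.
//
// Array layout follows R column-major convention throughout:
//   feature maps  x : H x W x C x N   (rows, cols, channels, batch)
//   conv weights  w : kh x kw x Cin x Cout
// Convolutions are "correlation" style (no kernel flip), zero-padded,
// strided.  Transposed convolution is expressed in R code through
// conv_bwd_input / conv_fwd duality, so only three kernels are needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one sample into column form: rows indexed by (ki, kj, c) with ki
// fastest (matching R's flattening of w), columns by output pixel (oi
// fastest).  x points at the sample's H*W*C block.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        double* dest = col.colptr(0) + row; // stride col.n_rows between cols
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          const bool jok = (j >= 0 && j < W);
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            const std::size_t cidx = (std::size_t)(oi + Ho * oj);
            double v = 0.0;
            if (jok && i >= 0 && i < H) v = xc[i + (std::size_t)j * H];
            dest[cidx * col.n_rows] = v;
          }
        }
      }
    }
  }
}

// scatter-add of column form back into an image (adjoint of im2col)
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        const double* src = col.colptr(0) + row;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            xc[i + (std::size_t)j * H] +=
              src[(std::size_t)(oi + Ho * oj) * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".nn_conv_fwd")]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], F = wd[3];
  if (Cin != C) stop("conv: input has %d channels, weight expects %d", C, Cin);
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv: non-positive output dims");

  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector y(Rcpp::no_init((std::size_t)Ho * Wo * F * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);

  arma::mat col(K, (std::size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C,
           kh, kw, stride, pad, Ho, Wo, col);
    // y_n (HoWo x F) = col' * Wm
    arma::mat yn(y.begin() + (std::size_t)n * Ho * Wo * F,
                 (std::size_t)Ho * Wo, F, false, true);
    yn = col.t() * Wm;
    for (int f = 0; f < F; ++f) yn.col(f) += b[f];
  }
  return y;
}

// Adjoint of the convolution w.r.t. its input, without needing the input
// itself (also the forward pass of a transposed convolution).
// dy: Ho x Wo x F x N; result: H x W x Cin x N.
// [[Rcpp::export(name = ".nn_conv_bwd_input")]]
NumericVector nn_conv_bwd_input(NumericVector w, NumericVector dy,
                                int stride, int pad, int H, int W) {
  IntegerVector wd = w.attr("dim"), yd = dy.attr("dim");
  const int kh = wd[0], kw = wd[1], C = wd[2], F = wd[3];
  const int Ho = yd[0], Wo = yd[1], N = yd[3];
  if (yd[2] != F) stop("conv_bwd_input: channel mismatch");
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);

  NumericVector dx((std::size_t)H * W * C * N); // zero-init
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + (std::size_t)n * Ho * Wo * F,
                  (std::size_t)Ho * Wo, F, false, true);
    arma::mat dcol = Wm * dyn.t();
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (std::size_t)n * H * W * C);
  }
  return dx;
}

// Gradients of a convolution. dy: Ho x Wo x F x N.  Returns any of
// dx (w.r.t. input), dw, db according to the want_* flags.
// [[Rcpp::export(name = ".nn_conv_bwd")]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad, bool want_dx, bool want_dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C;

  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector dx, dw;
  arma::mat dWm;
  if (want_dx) {
    dx = NumericVector((std::size_t)H * W * C * N); // zero-init
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  if (want_dw) dWm.zeros(K, F);
  arma::vec db(F, arma::fill::zeros);

  arma::mat col(K, (std::size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + (std::size_t)n * Ho * Wo * F,
                  (std::size_t)Ho * Wo, F, false, true);
    if (want_dw) {
      im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C,
             kh, kw, stride, pad, Ho, Wo, col);
      dWm += col * dyn;
    }
    if (want_dx) {
      arma::mat dcol = Wm * dyn.t(); // K x HoWo
      col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
             dx.begin() + (std::size_t)n * H * W * C);
    }
    db += arma::sum(dyn, 0).t();
  }

  List out = List::create(_["dx"] = R_NilValue, _["dw"] = R_NilValue,
                          _["db"] = NumericVector(db.begin(), db.end()));
  if (want_dx) out["dx"] = dx;
  if (want_dw) {
    dw = NumericVector(dWm.begin(), dWm.end());
    dw.attr("dim") = IntegerVector::create(kh, kw, C, F);
    out["dw"] = dw;
  }
  return out;
}
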