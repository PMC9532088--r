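// Minimal convolution / pooling kernels for the dense-block networks.
// Tensors are R arrays in (H, W, C, N) layout (column-major); convolution
// weights arrive flattened to a (kh*kw*Cin) x Cout matrix with the kernel-row
// index fastest, matching matrix(w, nrow = kh*kw*Cin) on an R array of
// dim c(kh, kw, Cin, Cout). Zero padding, stride 1, odd kernels only.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int pad, arma::mat& out) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int q = di + kh * (dj + kw * c);
        double* col = out.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          bool okj = sj >= 0 && sj < W;
          const double* xsj = xc + (std::size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + di - pad;
            col[i + (std::size_t)j * H] =
              (okj && si >= 0 && si < H) ? xsj[si] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int pad, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int q = di + kh * (dj + kw * c);
        const double* col = cols.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          double* xsj = xc + (std::size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + di - pad;
            if (si >= 0 && si < H) xsj[si] += col[i + (std::size_t)j * H];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericMatrix w,
                                 NumericVector bias, int kh, int kw) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  int F = w.ncol();
  int pad_h = (kh - 1) / 2, pad = pad_h; // square padding, odd kernels
  if (kh != kw) stop("kernel must be square");
  arma::mat wm(w.begin(), w.nrow(), F, false);
  NumericVector out((std::size_t)H * W * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat cols(H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C, kh, kw, pad, cols);
    arma::mat y = cols * wm;
    y.each_row() += arma::rowvec(bias.begin(), F, false);
    std::copy(y.begin(), y.end(), out.begin() + (std::size_t)n * H * W * F);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericMatrix w,
                         NumericVector dy, int kh, int kw) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  int F = w.ncol();
  int pad = (kh - 1) / 2;
  arma::mat wm(w.begin(), w.nrow(), F, false);
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dw(w.nrow(), F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  arma::mat cols(H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * H * W * C;
    arma::mat dyn(const_cast<double*>(dy.begin()) + (std::size_t)n * H * W * F,
                  H * W, F, false);
    im2col_one(xn, H, W, C, kh, kw, pad, cols);
    dw += cols.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcols = dyn * wm.t();
    col2im_one(dcols, H, W, C, kh, kw, pad,
               dx.begin() + (std::size_t)n * H * W * C);
  }
  NumericMatrix dwR(w.nrow(), F);
  std::copy(dw.begin(), dw.end(), dwR.begin());
  NumericVector dbR(F);
  std::copy(db.begin(), db.end(), dbR.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
}

// 2x2 average pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_forward(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((std::size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (std::size_t)(n * C + c) * H * W;
      double* ys = out.begin() + (std::size_t)(n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double* p = xs + (std::size_t)(2 * j) * H + 2 * i;
          ys[i + (std::size_t)j * Ho] =
            0.25 * (p[0] + p[1] + p[H] + p[H + 1]);
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector dy, int H, int W) {
  IntegerVector dm = dy.attr("dim");
  int Ho = dm[0], Wo = dm[1], C = dm[2], N = dm[3];
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* ds = dy.begin() + (std::size_t)(n * C + c) * Ho * Wo;
      double* xs = dx.begin() + (std::size_t)(n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double g = 0.25 * ds[i + (std::size_t)j * Ho];
          double* p = xs + (std::size_t)(2 * j) * H + 2 * i;
          p[0] += g; p[1] += g; p[H] += g; p[H + 1] += g;
        }
    }
  return dx;
}
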