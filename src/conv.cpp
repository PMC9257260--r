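// Same-padding, stride-1 2-D convolution via im2col + GEMM.
// Activations are column-major arrays with dim (H, W, C, B);
// kernels have dim (k, k, Cin, F).  k must be odd.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const double* x, int H, int W, int C, int k, mat& P) {
  const int pad = (k - 1) / 2;
  // P: (H*W) x (k*k*C), column q = dh + k*dw + k*k*c
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* col = P.colptr(dh + k * dw + k * k * c);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) col[h + H * w] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * sw;
          for (int h = 0; h < H; ++h) {
            int sh = h + dh - pad;
            col[h + H * w] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                   Rcpp::NumericVector bias) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[2] != C) Rcpp::stop("kernel input channels do not match input");
  mat Wm(w.begin(), k * k * C, F, false, true);
  rowvec bv(bias.begin(), F);
  Rcpp::NumericVector y((size_t)H * W * F * B);
  y.attr("dim") = Rcpp::IntegerVector::create(H, W, F, B);
  mat P(H * W, k * k * C);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, k, P);
    mat Y(y.begin() + (size_t)H * W * F * b, H * W, F, false, true);
    Y = P * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                          Rcpp::NumericVector dy) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], F = wd[3];
  const int pad = (k - 1) / 2;
  mat Wm(w.begin(), k * k * C, F, false, true);
  Rcpp::NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  mat dWm(k * k * C, F, fill::zeros);
  rowvec db(F, fill::zeros);
  mat P(H * W, k * k * C);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, k, P);
    mat dY(dy.begin() + (size_t)H * W * F * b, H * W, F, false, true);
    dWm += P.t() * dY;
    db += sum(dY, 0);
    mat dP = dY * Wm.t();   // (H*W) x (k*k*C)
    // col2im: scatter-add
    double* dxb = dx.begin() + (size_t)H * W * C * b;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxb + (size_t)H * W * c;
      for (int dw = 0; dw < k; ++dw) {
        for (int dh = 0; dh < k; ++dh) {
          const double* col = dP.colptr(dh + k * dw + k * k * c);
          for (int wq = 0; wq < W; ++wq) {
            int sw = wq + dw - pad;
            if (sw < 0 || sw >= W) continue;
            double* dst = dxc + (size_t)H * sw;
            for (int h = 0; h < H; ++h) {
              int sh = h + dh - pad;
              if (sh >= 0 && sh < H) dst[sh] += col[h + H * wq];
            }
          }
        }
      }
    }
  }
  Rcpp::NumericVector dw_out((size_t)k * k * C * F);
  dw_out.attr("dim") = Rcpp::IntegerVector::create(k, k, C, F);
  std::copy(dWm.begin(), dWm.end(), dw_out.begin());
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw_out,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
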