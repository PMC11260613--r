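// 2-D convolution kernels for the dose-prediction network.
// Layout: feature maps are R arrays of dim (H, W, C, N), column-major.
// Weights are matrices of dim (k*k*Cin) x Cout with row index
// kh + k*kw + k*k*c (kh, kw zero-based kernel offsets).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix for one sample: (Ho*Wo) x (k*k*Cin).
static void im2col(const double* x, int H, int W, int C,
                   int k, int pad, int stride,
                   int Ho, int Wo, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        double* dst = cols.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[ho + Ho * wo] = 0.0;
          } else {
            const double* src = xc + (std::size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride + kh - pad;
              dst[ho + Ho * wo] = (hi < 0 || hi >= H) ? 0.0 : src[hi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the gradient columns back onto the input grid (col2im).
static void col2im(const arma::mat& dcols, int H, int W, int C,
                   int k, int pad, int stride,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (std::size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        const double* src = dcols.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = dxc + (std::size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            if (hi >= 0 && hi < H) dst[hi] += src[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         int k, int pad, int stride) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  int Cout = w.ncol();
  int Ho = out_size(H, k, pad, stride), Wo = out_size(W, k, pad, stride);

  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat cols(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, pad, stride,
           Ho, Wo, cols);
    arma::mat yn = cols * wm;
    yn.each_row() += bv;
    std::copy(yn.begin(), yn.end(),
              y.begin() + (std::size_t)n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int k, int pad, int stride) {
  IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  int Cout = w.ncol();
  int Ho = out_size(H, k, pad, stride), Wo = out_size(W, k, pad, stride);

  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dw(k * k * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  arma::mat cols(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(dy.begin() + (std::size_t)n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false);
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, pad, stride,
           Ho, Wo, cols);
    dw += cols.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcols = dyn * wm.t();
    col2im(dcols, H, W, C, k, pad, stride, Ho, Wo,
           dx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(k * k * C, Cout, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
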