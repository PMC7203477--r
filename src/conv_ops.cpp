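// Batched 2-D "same" convolution via im2col + GEMM.
//
// Activation tensors are passed as numeric arrays with dim (H*W, C, B):
// each feature map is an H x W matrix flattened column-major, H = EEG
// channels, W = time bins.  Weights are (C*kh*kw) x F matrices whose row
// order is (channel-major, then kernel column, then kernel row), matching
// the im2col layout built here.  Only this file and the R layer code need
// to agree on that order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, arma::mat& xcol) {
  // xcol: (H*W) x (C*kh*kw), zero-padded "same" with odd kernels
  const int ph = kh / 2, pw = kw / 2;
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int dc = -pw; dc <= pw; ++dc) {
      for (int dr = -ph; dr <= ph; ++dr, ++col) {
        double* out = xcol.colptr(col);
        for (int j = 0; j < W; ++j) {
          int sj = j + dc;
          double* outj = out + (std::size_t)j * H;
          if (sj < 0 || sj >= W) {
            std::memset(outj, 0, sizeof(double) * H);
            continue;
          }
          const double* xj = xc + (std::size_t)sj * H;
          int i0 = std::max(0, -dr), i1 = std::min(H, H - dr);
          if (i0 > 0) std::memset(outj, 0, sizeof(double) * i0);
          for (int i = i0; i < i1; ++i) outj[i] = xj[i + dr];
          if (i1 < H) std::memset(outj + i1, 0, sizeof(double) * (H - i1));
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, int H, int W,
                         NumericMatrix wmat, NumericVector bias,
                         int kh, int kw) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0], C = xd[1], B = xd[2];
  const int CK = wmat.nrow(), F = wmat.ncol();
  if (HW != H * W) stop("spatial size mismatch");
  if (CK != C * kh * kw) stop("weight rows != C*kh*kw");

  NumericVector y(Dimension(HW, F, B));
  arma::mat Wm(wmat.begin(), CK, F, false, true);
  arma::rowvec b(bias.begin(), F);
  arma::mat xcol(HW, CK);
  for (int bidx = 0; bidx < B; ++bidx) {
    im2col_one(x.begin() + (std::size_t)bidx * HW * C, H, W, C, kh, kw, xcol);
    arma::mat yb(y.begin() + (std::size_t)bidx * HW * F, HW, F, false, true);
    yb = xcol * Wm;
    yb.each_row() += b;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector dy, NumericMatrix wmat,
                int H, int W, int kh, int kw) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0], C = xd[1], B = xd[2];
  const int CK = wmat.nrow(), F = wmat.ncol();

  NumericVector dx(Dimension(HW, C, B));
  arma::mat Wm(wmat.begin(), CK, F, false, true);
  arma::mat dW(CK, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  arma::mat xcol(HW, CK);

  // For stride-1 symmetric zero padding, the input gradient is itself a
  // "same" convolution of dy with the 180-degree-rotated kernels, with
  // input/output channel roles swapped:
  //   Wrot[(f, kk-1-k), c] = W[(c, k), f]
  const int kk = kh * kw;
  arma::mat Wrot(F * kk, C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < kk; ++k) {
      for (int f = 0; f < F; ++f) {
        Wrot((std::size_t)f * kk + (kk - 1 - k), c) =
          Wm((std::size_t)c * kk + k, f);
      }
    }
  }
  arma::mat dycol(HW, F * kk);

  for (int bidx = 0; bidx < B; ++bidx) {
    arma::mat dyb(const_cast<double*>(dy.begin()) + (std::size_t)bidx * HW * F,
                  HW, F, false, true);
    im2col_one(x.begin() + (std::size_t)bidx * HW * C, H, W, C, kh, kw, xcol);
    dW += xcol.t() * dyb;
    db += arma::sum(dyb, 0);
    im2col_one(dy.begin() + (std::size_t)bidx * HW * F, H, W, F, kh, kw,
               dycol);
    arma::mat dxb(dx.begin() + (std::size_t)bidx * HW * C, HW, C, false, true);
    dxb = dycol * Wrot;
  }
  return List::create(Named("dx") = dx,
                      Named("dw") = NumericMatrix(CK, F, dW.begin()),
                      Named("db") = NumericVector(db.begin(), db.end()));
}
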