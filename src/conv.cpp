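// Convolution forward/backward kernels for the UNet engine.
//
// Layout convention (matching R column-major arrays):
//   activations x : H x W x C x N
//   weights     w : k x k x Cin x Cout   (row offset fastest)
//   im2col matrix : (H*W) x (k*k*Cin), column j = kr + k*kc + k*k*ci
// "Same" zero padding with pad = k / 2; stride 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_fill(const double* x, int H, int W, int Cin, int k, int pad,
                        arma::mat& Xc) {
  const int HW = H * W;
  Xc.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (std::size_t)ci * HW;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int j = kr + k * kc + k * k * ci;
        const int dr = kr - pad, dc = kc - pad;
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        double* col = Xc.colptr(j);
        for (int c = c0; c < c1; ++c) {
          const double* src = xc + (std::size_t)(c + dc) * H + (r0 + dr);
          double* dst = col + (std::size_t)c * H + r0;
          std::copy(src, src + (r1 - r0), dst);
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& Dxc, int H, int W, int Cin, int k,
                       int pad, double* dx) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (std::size_t)ci * HW;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int j = kr + k * kc + k * k * ci;
        const int dr = kr - pad, dc = kc - pad;
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const double* col = Dxc.colptr(j);
        for (int c = c0; c < c1; ++c) {
          double* dst = xc + (std::size_t)(c + dc) * H + (r0 + dr);
          const double* src = col + (std::size_t)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = k / 2, HW = H * W;
  if (wd[2] != Cin) stop("conv_fwd: channel mismatch");
  NumericVector out((std::size_t)HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), k * k * Cin, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat Xc(HW, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin() + (std::size_t)n * HW * Cin, H, W, Cin, k, pad, Xc);
    arma::mat Y = Xc * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), out.begin() + (std::size_t)n * HW * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = k / 2, HW = H * W;
  NumericVector dx((std::size_t)HW * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw((std::size_t)k * k * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), k * k * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), k * k * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat Xc(HW, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin() + (std::size_t)n * HW * Cin, H, W, Cin, k, pad, Xc);
    arma::mat Dy(dy.begin() + (std::size_t)n * HW * Cout, HW, Cout, false, true);
    dWm += Xc.t() * Dy;
    dbv += arma::sum(Dy, 0);
    arma::mat Dxc = Dy * Wm.t();
    col2im_add(Dxc, H, W, Cin, k, pad, dx.begin() + (std::size_t)n * HW * Cin);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
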