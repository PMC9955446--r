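// Minimal conv / pooling kernels used by the residual classifier.
// Layout conventions (R column-major):
//   activations: array(H, W, C, N)
//   conv weights: flattened to a (kh*kw*Cin) x Cout matrix whose row index
//   is ki + kh*(kj + kw*ci), i.e. matrix(w_array_khkwCinCout, kh*kw*Cin, Cout).
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride + kj - pad;
          const bool win = (w >= 0 && w < W);
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride + ki - pad;
            col.at(r, oh + (size_t)Ho * ow) =
              (win && h >= 0 && h < H) ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& col, double* dx, int H, int W, int C,
                       int kh, int kw, int pad, int stride, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride + kj - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride + ki - pad;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += col.at(r, oh + (size_t)Ho * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix wmat, NumericVector bias,
                         int kh, int kw, int pad, int stride) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = wmat.ncol();
  const arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
  const arma::rowvec b(bias.begin(), Cout);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  arma::mat col(kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, stride,
           Ho, Wo, col);
    arma::mat o = col.t() * Wm;  // (Ho*Wo) x Cout
    o.each_row() += b;
    std::copy(o.begin(), o.end(), out.begin() + (size_t)Ho * Wo * Cout * n);
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, IntegerVector xdim, NumericMatrix wmat,
                NumericVector dy, int kh, int kw, int pad, int stride,
                bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = wmat.ncol();
  const int K = wmat.nrow();
  const arma::mat Wm(wmat.begin(), K, Cout, false);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : (size_t)0);
  arma::mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                        (size_t)Ho * Wo, Cout, false);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, stride,
           Ho, Wo, col);
    dW += col * dyn;
    db += arma::sum(dyn, 0);
    if (need_dx) {
      arma::mat dcol = Wm * dyn.t();  // K x (Ho*Wo)
      col2im_acc(dcol, dx.begin() + (size_t)H * W * C * n, H, W, C,
                 kh, kw, pad, stride, Ho, Wo);
    }
  }
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dw"] = wrap(dW), _["db"] = wrap(arma::vec(db.t())),
                      _["dx"] = dx);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      const double* xc = x.begin() + base;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          const int h0 = 2 * oh, w0 = 2 * ow;
          size_t best = h0 + (size_t)H * w0;
          double bv = xc[best];
          const size_t cand[3] = {h0 + 1 + (size_t)H * w0,
                                  h0 + (size_t)H * (w0 + 1),
                                  h0 + 1 + (size_t)H * (w0 + 1)};
          for (int k = 0; k < 3; ++k)
            if (xc[cand[k]] > bv) { bv = xc[cand[k]]; best = cand[k]; }
          out[p] = bv;
          idx[p] = (int)(base + best);  // 0-based global index into x
          ++p;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector xdim) {
  const size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
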