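// Low-level tensor kernels for the detector.
//
// Tensor layout matches R arrays: dim (H, W, C, N), column-major, H fastest.
// Convolution weights are a (Cout x K*K*Cin) matrix whose column index is
// c * K * K + kx * K + ky  (channel-major, then x offset, then y offset).
// im2col column index is ox * Hout + oy, so a (Hout*Wout x Cout) matrix is
// memory-identical to an (Hout, Wout, Cout) array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void im2col_one(const double* x, int H, int W, int C,
                              int K, int stride, int pad,
                              int Hout, int Wout, arma::mat& cols) {
  // cols: (K*K*C) x (Hout*Wout), already allocated
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        int row = c * K * K + kx * K + ky;
        for (int ox = 0; ox < Wout; ++ox) {
          int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          const double* xcol = xc + (size_t)ix * H;
          double* dst = cols.colptr(0) + (size_t)row;
          for (int oy = 0; oy < Hout; ++oy) {
            int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            dst[(size_t)(ox * Hout + oy) * cols.n_rows] = xcol[iy];
          }
        }
      }
    }
  }
}

static inline void col2im_one(const arma::mat& cols, int H, int W, int C,
                              int K, int stride, int pad,
                              int Hout, int Wout, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        int row = c * K * K + kx * K + ky;
        for (int ox = 0; ox < Wout; ++ox) {
          int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          double* xcol = xc + (size_t)ix * H;
          const double* src = cols.colptr(0) + (size_t)row;
          for (int oy = 0; oy < Hout; ++oy) {
            int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            xcol[iy] += src[(size_t)(ox * Hout + oy) * cols.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericMatrix wmat, NumericVector bias,
                       int K, int stride, int pad) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = wmat.nrow();
  if (wmat.ncol() != K * K * C) stop("conv_fwd: weight/input channel mismatch");
  int Hout = (H + 2 * pad - K) / stride + 1;
  int Wout = (W + 2 * pad - K) / stride + 1;
  NumericVector y = make4(Hout, Wout, Cout, N);
  arma::mat Wm(wmat.begin(), Cout, K * K * C, false);
  arma::mat cols(K * K * C, Hout * Wout);
  bool has_bias = bias.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad,
               Hout, Wout, cols);
    arma::mat ym = cols.t() * Wm.t();  // (Hout*Wout) x Cout
    if (has_bias) ym.each_row() += arma::rowvec(bias.begin(), Cout, false);
    std::copy(ym.memptr(), ym.memptr() + ym.n_elem,
              y.begin() + (size_t)n * Hout * Wout * Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericMatrix wmat, NumericVector dy,
              int K, int stride, int pad, bool need_dx) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = wmat.nrow();
  int Hout = (H + 2 * pad - K) / stride + 1;
  int Wout = (W + 2 * pad - K) / stride + 1;
  arma::mat Wm(wmat.begin(), Cout, K * K * C, false);
  NumericVector dx;
  if (need_dx) { dx = make4(H, W, C, N); }
  arma::mat dW(Cout, K * K * C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(K * K * C, Hout * Wout);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(dy.begin() + (size_t)n * Hout * Wout * Cout,
                  Hout * Wout, Cout, false);  // (HW x Cout)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad,
               Hout, Wout, cols);
    dW += dym.t() * cols.t();
    db += arma::sum(dym, 0).t();
    if (need_dx) {
      arma::mat dcols = Wm.t() * dym.t();  // (KKC x HW)
      col2im_one(dcols, H, W, C, K, stride, pad, Hout, Wout,
                 dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(Cout, K * K * C, dW.memptr()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int K, int stride, int pad) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Hout = (H + 2 * pad - K) / stride + 1;
  int Wout = (W + 2 * pad - K) / stride + 1;
  NumericVector y = make4(Hout, Wout, C, N);
  IntegerVector idx(y.size());  // 1-based linear index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int ox = 0; ox < Wout; ++ox) {
        for (int oy = 0; oy < Hout; ++oy) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int kx = 0; kx < K; ++kx) {
            int ix = ox * stride - pad + kx;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < K; ++ky) {
              int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= H) continue;
              double v = xc[(size_t)ix * H + iy];
              if (v > best) { best = v; bi = (size_t)ix * H + iy; }
            }
          }
          y[o + (size_t)ox * Hout + oy] = best;
          idx[o + (size_t)ox * Hout + oy] = (int)(base + bi) + 1;
        }
      }
      o += (size_t)Hout * Wout;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".scatter_add")]]
NumericVector scatter_add(NumericVector dy, IntegerVector idx, int n_out,
                          IntegerVector out_dim) {
  NumericVector dx(n_out);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = out_dim;
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  NumericVector y = make4(2 * H, 2 * W, C, N);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* yp = y.begin() + p * 4 * H * W;
    for (int ix = 0; ix < W; ++ix) {
      for (int iy = 0; iy < H; ++iy) {
        double v = xp[(size_t)ix * H + iy];
        size_t b = (size_t)(2 * ix) * 2 * H + 2 * iy;
        yp[b] = v; yp[b + 1] = v;
        yp[b + 2 * H] = v; yp[b + 2 * H + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector dims = dy.attr("dim");
  int H2 = dims[0], W2 = dims[1], C = dims[2], N = dims[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx = make4(H, W, C, N);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dyp = dy.begin() + p * H2 * W2;
    double* dxp = dx.begin() + p * H * W;
    for (int ix = 0; ix < W; ++ix) {
      for (int iy = 0; iy < H; ++iy) {
        size_t b = (size_t)(2 * ix) * H2 + 2 * iy;
        dxp[(size_t)ix * H + iy] =
          dyp[b] + dyp[b + 1] + dyp[b + H2] + dyp[b + H2 + 1];
      }
    }
  }
  return dx;
}

// Global max over the spatial axes with argmax: x (H,W,C,N) -> y (C,N),
// idx = 1-based linear index within the (H,W) plane.
// [[Rcpp::export(name = ".spat_max")]]
List spat_max(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t HW = (size_t)H * W;
  NumericMatrix y(C, N);
  IntegerMatrix idx(C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      double best = xc[0]; size_t bi = 0;
      for (size_t p = 1; p < HW; ++p) if (xc[p] > best) { best = xc[p]; bi = p; }
      y(c, n) = best; idx(c, n) = (int)bi + 1;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Max over the channel axis with argmax: x (H,W,C,N) -> y (H,W,1,N), idx of c.
// [[Rcpp::export(name = ".chan_max")]]
List chan_max(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t HW = (size_t)H * W;
  NumericVector y = make4(H, W, 1, N);
  IntegerVector idx(HW * N);  // 1-based channel index
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    double* yn = y.begin() + (size_t)n * HW;
    int* in = idx.begin() + (size_t)n * HW;
    for (size_t p = 0; p < HW; ++p) { yn[p] = xn[p]; in[p] = 1; }
    for (int c = 1; c < C; ++c) {
      const double* xc = xn + (size_t)c * HW;
      for (size_t p = 0; p < HW; ++p) {
        if (xc[p] > yn[p]) { yn[p] = xc[p]; in[p] = c + 1; }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}
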