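// Same-padded 2D convolution forward/backward used by the residual
// U-net. Tensors are R arrays in (H, W, C, N) order (column-major, H
// fastest); weights are (k, k, Cin, Cout). im2col + GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat weight_mat(const NumericVector& w, int k, int cin, int cout) {
  // column q = ci*k*k + dj*k + di ; arma::mat K x Cout
  arma::mat W(k * k * cin, cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          W(ci * k * k + dj * k + di, co) =
            wp[di + k * (dj + k * (ci + cin * co))];
  return W;
}

static void im2col(const double* x, int H, int W, int C, int n_off,
                   int k, int pad, arma::mat& P) {
  // P is (H*W) x (k*k*C); x offset already points at sample n
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + n_off + (size_t)ci * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int q = ci * k * k + dj * k + di;
        double* col = P.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) col[i + j * H] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + di - pad;
            col[i + j * H] = (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], cin = wd[2], cout = wd[3];
  if (cin != C) stop("conv2d_fwd: weight Cin %d != input C %d", cin, C);
  int pad = (k - 1) / 2;
  NumericVector y(NumericVector((size_t)H * Wd * cout * N));
  y.attr("dim") = IntegerVector::create(H, Wd, cout, N);
  arma::mat Wm = weight_mat(w, k, cin, cout);
  arma::rowvec bv(cout);
  for (int c = 0; c < cout; ++c) bv(c) = b[c];
  arma::mat P(H * Wd, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, Wd, C, (size_t)n * H * Wd * C, k, pad, P);
    arma::mat Y = P * Wm;
    Y.each_row() += bv;
    std::memcpy(y.begin() + (size_t)n * H * Wd * cout, Y.memptr(),
                sizeof(double) * H * Wd * cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], cin = wd[2], cout = wd[3];
  int pad = (k - 1) / 2;
  arma::mat Wm = weight_mat(w, k, cin, cout);
  arma::mat gWm(k * k * C, cout, arma::fill::zeros);
  arma::rowvec gb(cout, arma::fill::zeros);
  NumericVector gx(NumericVector((size_t)H * Wd * C * N));
  gx.attr("dim") = IntegerVector::create(H, Wd, C, N);
  arma::mat P(H * Wd, k * k * C);
  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)n * H * Wd * C;
    size_t yoff = (size_t)n * H * Wd * cout;
    im2col(x.begin(), H, Wd, C, xoff, k, pad, P);
    arma::mat Gy(const_cast<double*>(gy.begin()) + yoff, H * Wd, cout, false, true);
    gWm += P.t() * Gy;
    gb += arma::sum(Gy, 0);
    arma::mat GP = Gy * Wm.t();  // (H*W) x (k*k*C)
    // col2im scatter-add
    double* gxp = gx.begin() + xoff;
    for (int ci = 0; ci < C; ++ci) {
      double* gxc = gxp + (size_t)ci * H * Wd;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          int q = ci * k * k + dj * k + di;
          const double* col = GP.colptr(q);
          for (int j = 0; j < Wd; ++j) {
            int sj = j + dj - pad;
            if (sj < 0 || sj >= Wd) continue;
            double* dst = gxc + (size_t)sj * H;
            for (int i = 0; i < H; ++i) {
              int si = i + di - pad;
              if (si >= 0 && si < H) dst[si] += col[i + j * H];
            }
          }
        }
      }
    }
  }
  // repack gW to (k, k, Cin, Cout)
  NumericVector gw(NumericVector((size_t)k * k * C * cout));
  gw.attr("dim") = IntegerVector::create(k, k, C, cout);
  double* gwp = gw.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          gwp[di + k * (dj + k * (ci + C * co))] = gWm(ci * k * k + dj * k + di, co);
  NumericVector gbv(cout);
  for (int c = 0; c < cout; ++c) gbv[c] = gb(c);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
}
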