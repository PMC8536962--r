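// Low-level network kernels. All tensors are R arrays in column-major
// (H, W, C, B) layout; convolution kernels are (kh, kw, Cin, Cout).
// Convolutions are size-preserving (odd kernels, zero padding); the
// transposed convolution is the non-overlapping 2x2/stride-2 case, so both
// reduce to a single GEMM per image via im2col / col2im.
//
// Everything here is single-threaded and allocation-deterministic: results
// are a pure function of the inputs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* xb, arma::mat& M,
                   int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = xb + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * (dw + kw * c);
        double* Mcol = M.colptr(col);
        const int h0 = dh - ph, w0 = dw - pw;
        for (int ww = 0; ww < W; ++ww) {
          const int w2 = ww + w0;
          if (w2 < 0 || w2 >= W) continue;
          const double* src = xc + (size_t)H * w2;
          double* dst = Mcol + (size_t)H * ww;
          const int hlo = std::max(0, -h0);
          const int hhi = std::min(H, H - h0);
          for (int hh = hlo; hh < hhi; ++hh) dst[hh] = src[hh + h0];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int K = kh * kw * C;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector y((size_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat M(H * W, K, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + (size_t)H * W * C * bb, M, H, W, C, kh, kw);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * bb, H * W, Cout, false, true);
    Y = M * Wm;
    for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kh * kw * C;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  NumericVector db(Cout);
  arma::mat M(H * W, K, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + (size_t)H * W * C * bb, M, H, W, C, kh, kw);
    arma::mat dY(dy.begin() + (size_t)H * W * Cout * bb, H * W, Cout, false, true);
    dWm += M.t() * dY;
    for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dY.col(o));
    arma::mat dXm = dY * Wm.t();  // (H*W) x K
    double* dxb = dx.begin() + (size_t)H * W * C * bb;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxb + (size_t)H * W * c;
      for (int dwk = 0; dwk < kw; ++dwk) {
        for (int dh = 0; dh < kh; ++dh) {
          const int col = dh + kh * (dwk + kw * c);
          const double* Dcol = dXm.colptr(col);
          const int h0 = dh - ph, w0 = dwk - pw;
          for (int ww = 0; ww < W; ++ww) {
            const int w2 = ww + w0;
            if (w2 < 0 || w2 >= W) continue;
            double* dst = dxc + (size_t)H * w2;
            const double* src = Dcol + (size_t)H * ww;
            const int hlo = std::max(0, -h0);
            const int hhi = std::min(H, H - h0);
            for (int hh = hlo; hh < hhi; ++hh) dst[hh + h0] += src[hh];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)H2 * W2 * C * B);
  IntegerVector idx((size_t)H2 * W2 * C * B);  // 0-based offsets into x
  IntegerVector yd = IntegerVector::create(H2, W2, C, B);
  y.attr("dim") = yd;
  idx.attr("dim") = yd;
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * bb);
      for (int ww = 0; ww < W2; ++ww) {
        for (int hh = 0; hh < H2; ++hh, ++o) {
          size_t best = base + 2 * hh + (size_t)H * (2 * ww);
          double bv = x[best];
          const size_t cand[3] = {base + 2 * hh + 1 + (size_t)H * (2 * ww),
                                  base + 2 * hh + (size_t)H * (2 * ww + 1),
                                  base + 2 * hh + 1 + (size_t)H * (2 * ww + 1)};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          y[o] = bv;
          idx[o] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < idx.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// kernel reshape for the 2x2/stride-2 transposed convolution:
// K2(c, dh + 2*dw + 4*o) = w(dh, dw, c, o)
static arma::mat convt2_kmat(const NumericVector& w, int Cin, int Cout) {
  arma::mat K2(Cin, 4 * Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int dw2 = 0; dw2 < 2; ++dw2)
        for (int dh = 0; dh < 2; ++dh)
          K2(c, dh + 2 * dw2 + 4 * o) = w[dh + 2 * (dw2 + 2 * (c + (size_t)Cin * o))];
  return K2;
}

// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  arma::mat K2 = convt2_kmat(w, C, Cout);
  NumericVector y((size_t)H2 * W2 * Cout * B);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, B);
  for (int bb = 0; bb < B; ++bb) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * bb,
                 H * W, C, false, true);
    arma::mat Y2 = Xm * K2;  // (H*W) x (4*Cout)
    double* yb = y.begin() + (size_t)H2 * W2 * Cout * bb;
    for (int o = 0; o < Cout; ++o) {
      double* yo = yb + (size_t)H2 * W2 * o;
      for (int dw2 = 0; dw2 < 2; ++dw2) {
        for (int dh = 0; dh < 2; ++dh) {
          const double* col = Y2.colptr(dh + 2 * dw2 + 4 * o);
          for (int ww = 0; ww < W; ++ww) {
            double* dst = yo + (size_t)H2 * (2 * ww + dw2) + dh;
            const double* src = col + (size_t)H * ww;
            for (int hh = 0; hh < H; ++hh) dst[2 * hh] = src[hh] + b[o];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  arma::mat K2 = convt2_kmat(w, C, Cout);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)4 * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dK2(C, 4 * Cout, arma::fill::zeros);
  arma::mat dY2(H * W, 4 * Cout);
  for (int bb = 0; bb < B; ++bb) {
    const double* dyb = dy.begin() + (size_t)H2 * W2 * Cout * bb;
    for (int o = 0; o < Cout; ++o) {
      const double* dyo = dyb + (size_t)H2 * W2 * o;
      double s = 0.0;
      for (size_t i = 0; i < (size_t)H2 * W2; ++i) s += dyo[i];
      db[o] += s;
      for (int dw2 = 0; dw2 < 2; ++dw2) {
        for (int dh = 0; dh < 2; ++dh) {
          double* col = dY2.colptr(dh + 2 * dw2 + 4 * o);
          for (int ww = 0; ww < W; ++ww) {
            const double* src = dyo + (size_t)H2 * (2 * ww + dw2) + dh;
            double* dst = col + (size_t)H * ww;
            for (int hh = 0; hh < H; ++hh) dst[hh] = src[2 * hh];
          }
        }
      }
    }
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * bb,
                 H * W, C, false, true);
    dK2 += Xm.t() * dY2;
    arma::mat dXm(dx.begin() + (size_t)H * W * C * bb, H * W, C, false, true);
    dXm = dY2 * K2.t();
  }
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int dw2 = 0; dw2 < 2; ++dw2)
        for (int dh = 0; dh < 2; ++dh)
          dw[dh + 2 * (dw2 + 2 * (c + (size_t)C * o))] = dK2(c, dh + 2 * dw2 + 4 * o);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
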