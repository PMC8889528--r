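#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor layout: activations are R arrays with dim (H, W, C, N), column-major;
// convolution weights have dim (kh, kw, Cin, Cout).

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col: columns ordered (ho fastest, wo, n); rows ordered (dh fastest, dw, c).
static arma::mat im2col(const double *x, int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int K = kh * kw * C;
  arma::mat col(K, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword ccol = (arma::uword)n * Ho * Wo + (arma::uword)wo * Ho + ho;
        double *dst = col.colptr(ccol);
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (size_t)c * H * W;
          for (int dw = 0; dw < kw; ++dw) {
            int w = wo * stride + dw - pad;
            for (int dh = 0; dh < kh; ++dh) {
              int h = ho * stride + dh - pad;
              if (h >= 0 && h < H && w >= 0 && w < W)
                dst[dh + kh * (dw + kw * c)] = xc[h + (size_t)H * w];
            }
          }
        }
      }
    }
  }
  return col;
}

static arma::mat weight_mat(const NumericVector &w, int kh, int kw, int Cin, int Cout) {
  arma::mat Wm(Cout, kh * kw * Cin);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh)
          Wm(o, dh + kh * (dw + kw * c)) =
            w[dh + kh * ((size_t)dw + kw * ((size_t)c + (size_t)Cin * o))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector nn_conv_forward(NumericVector x, NumericVector w, NumericVector b,
                              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch (%d vs %d)", Cin, C);
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv: spatial output collapsed to zero");
  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm = weight_mat(w, kh, kw, Cin, Cout);
  arma::mat Y = Wm * col;            // Cout x (Ho*Wo*N)
  Y.each_col() += arma::vec(b.begin(), Cout);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double *op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword m = (arma::uword)n * Ho * Wo + (arma::uword)wo * Ho + ho;
        for (int o = 0; o < Cout; ++o)
          op[ho + (size_t)Ho * (wo + (size_t)Wo * (o + (size_t)Cout * n))] = Y(o, m);
      }
  return out;
}

// [[Rcpp::export]]
List nn_conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm = weight_mat(w, kh, kw, Cin, Cout);

  arma::mat dYm(Cout, (arma::uword)Ho * Wo * N);
  const double *dp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword m = (arma::uword)n * Ho * Wo + (arma::uword)wo * Ho + ho;
        for (int o = 0; o < Cout; ++o)
          dYm(o, m) = dp[ho + (size_t)Ho * (wo + (size_t)Wo * (o + (size_t)Cout * n))];
      }

  arma::mat dWm = dYm * col.t();     // Cout x K
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dcol = Wm.t() * dYm;     // K x (Ho*Wo*N)

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  double *dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double *dxn = dxp + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword ccol = (arma::uword)n * Ho * Wo + (arma::uword)wo * Ho + ho;
        const double *src = dcol.colptr(ccol);
        for (int c = 0; c < C; ++c) {
          double *dxc = dxn + (size_t)c * H * W;
          for (int dw = 0; dw < kw; ++dw) {
            int ww = wo * stride + dw - pad;
            for (int dh = 0; dh < kh; ++dh) {
              int hh = ho * stride + dh - pad;
              if (hh >= 0 && hh < H && ww >= 0 && ww < W)
                dxc[hh + (size_t)H * ww] += src[dh + kh * (dw + kw * c)];
            }
          }
        }
      }
  }

  NumericVector dwv((size_t)kh * kw * Cin * Cout);
  dwv.attr("dim") = wd;
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh)
          dwv[dh + kh * ((size_t)dw + kw * ((size_t)c + (size_t)Cin * o))] =
            dWm(o, dh + kh * (dw + kw * c));

  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling; padded cells (value -Inf) never win because windows always
// contain at least one in-bounds pixel when pad < size.
// [[Rcpp::export]]
List nn_maxpool_forward(NumericVector x, int size, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, size, stride, pad), Wo = out_size(W, size, stride, pad);
  if (Ho < 1 || Wo < 1) stop("maxpool: spatial output collapsed to zero");
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (size_t)H * W * (c + (size_t)C * n);
      size_t plane = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int dw = 0; dw < size; ++dw) {
            int w = wo * stride + dw - pad;
            if (w < 0 || w >= W) continue;
            for (int dh = 0; dh < size; ++dh) {
              int h = ho * stride + dh - pad;
              if (h < 0 || h >= H) continue;
              double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; besti = plane + h + (size_t)H * w; }
            }
          }
          size_t o = ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          y[o] = best;
          idx[o] = (int)besti;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_backward(IntegerVector idx, NumericVector dy,
                                  IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}
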