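// Numerical primitives for the segmentation networks.
//
// Array layout convention (column-major, matching R): feature tensors are
// [H, W, C, N]; a convolution weight bank is stored as the im2col matrix
// [kh*kw*Cin, Cout] with row index q = ki + kh*(kj + kw*c).
// All forward ops have matching analytic backward ops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int n) {
  NumericVector v((R_xlen_t)a * b * c * n);
  v.attr("dim") = IntegerVector::create(a, b, c, n);
  return v;
}

static inline int conv_out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill `col` ([Ho*Wo, kh*kw*Cin]) from sample n of x ([H,W,C,N]).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        double* dst = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          const bool win = (w >= 0 && w < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ki;
            double v = 0.0;
            if (win && h >= 0 && h < H) v = xc[h + (size_t)H * w];
            dst[ho + (size_t)Ho * wo] = v;
          }
        }
      }
    }
  }
}

// Scatter-add `col` back into sample n of dx (transpose of im2col).
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        const double* src = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += src[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericMatrix Wmat,
                             NumericVector bias, int kh, int kw,
                             int stride, int pad) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("conv2d: input must be [H,W,C,N]");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = kh * kw * C;
  if (Wmat.nrow() != K) stop("conv2d: weight rows != kh*kw*Cin");
  const int Cout = Wmat.ncol();
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::mat Wm(Wmat.begin(), K, Cout, false, true);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  arma::mat col(Ho * Wo, K);
  const bool has_b = bias.size() == Cout;

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat yn(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout,
                 false, true);
    yn = col * Wm;
    if (has_b)
      for (int co = 0; co < Cout; ++co) yn.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericMatrix Wmat, NumericVector dy,
                    int kh, int kw, int stride, int pad, bool need_dx,
                    bool need_db) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = kh * kw * C;
  const int Cout = Wmat.ncol();
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);

  arma::mat Wm(Wmat.begin(), K, Cout, false, true);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) dx = alloc4(H, W, C, N);
  arma::mat col(Ho * Wo, K);

  for (int n = 0; n < N; ++n) {
    arma::mat dyn(dy.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout,
                  false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    dW += col.t() * dyn;
    if (need_db) db += arma::sum(dyn, 0).t();
    if (need_dx) {
      arma::mat dcol = dyn * Wm.t();
      col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
             dx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(K, Cout, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax offsets
// (0..3: dh + 2*dw) for the backward scatter.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xs = xp + (size_t)H * W * p;
    double* ys = yp + (size_t)Ho * Wo * p;
    int* is = ip + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int best = 0;
        double bv = xs[2 * ho + (size_t)H * (2 * wo)];
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const double v = xs[2 * ho + dh + (size_t)H * (2 * wo + dw)];
            if (v > bv) { bv = v; best = dh + 2 * dw; }
          }
        ys[ho + (size_t)Ho * wo] = bv;
        is[ho + (size_t)Ho * wo] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho * 2, W = Wo * 2;
  NumericVector dx = alloc4(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dys = dyp + (size_t)Ho * Wo * p;
    const int* is = ip + (size_t)Ho * Wo * p;
    double* dxs = dxp + (size_t)H * W * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int a = is[ho + (size_t)Ho * wo];
        const int dh = a % 2, dw = a / 2;
        dxs[2 * ho + dh + (size_t)H * (2 * wo + dw)] +=
            dys[ho + (size_t)Ho * wo];
      }
  }
  return dx;
}

// Bilinear 2x upsampling (half-pixel centers, i.e. align_corners = FALSE).
static void up2_coeffs(int Ho, int H, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int ho = 0; ho < Ho; ++ho) {
    double s = (ho + 0.5) / 2.0 - 0.5;
    double f = std::floor(s);
    double w = s - f;
    int a = (int)f, b = a + 1;
    if (a < 0) { a = 0; }
    if (b > H - 1) { b = H - 1; }
    if (a > H - 1) a = H - 1;
    i0[ho] = a; i1[ho] = b; w1[ho] = w;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, C, N);
  std::vector<int> hi0, hi1, wi0, wi1;
  std::vector<double> hw1, ww1;
  up2_coeffs(Ho, H, hi0, hi1, hw1);
  up2_coeffs(Wo, W, wi0, wi1, ww1);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xs = x.begin() + (size_t)H * W * p;
    double* ys = y.begin() + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wi0[wo], w1i = wi1[wo];
      const double ww = ww1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double hw = hw1[ho];
        const double v00 = xs[hi0[ho] + (size_t)H * w0];
        const double v10 = xs[hi1[ho] + (size_t)H * w0];
        const double v01 = xs[hi0[ho] + (size_t)H * w1i];
        const double v11 = xs[hi1[ho] + (size_t)H * w1i];
        ys[ho + (size_t)Ho * wo] =
            (1 - hw) * ((1 - ww) * v00 + ww * v01) +
            hw * ((1 - ww) * v10 + ww * v11);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx = alloc4(H, W, C, N);
  std::vector<int> hi0, hi1, wi0, wi1;
  std::vector<double> hw1, ww1;
  up2_coeffs(Ho, H, hi0, hi1, hw1);
  up2_coeffs(Wo, W, wi0, wi1, ww1);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dys = dy.begin() + (size_t)Ho * Wo * p;
    double* dxs = dx.begin() + (size_t)H * W * p;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wi0[wo], w1i = wi1[wo];
      const double ww = ww1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dys[ho + (size_t)Ho * wo];
        const double hw = hw1[ho];
        dxs[hi0[ho] + (size_t)H * w0] += (1 - hw) * (1 - ww) * g;
        dxs[hi1[ho] + (size_t)H * w0] += hw * (1 - ww) * g;
        dxs[hi0[ho] + (size_t)H * w1i] += (1 - hw) * ww * g;
        dxs[hi1[ho] + (size_t)H * w1i] += hw * ww * g;
      }
    }
  }
  return dx;
}

// In-place Adam update for one parameter bank. The moment buffers and the
// parameter vector are owned by the layer environment and updated without
// allocation.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double eps, int t) {
  const R_xlen_t n = p.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
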