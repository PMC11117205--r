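// Convolution kernels for the keypoint-counting network.
//
// Memory layout (column-major, matching R arrays):
//   feature maps  x[C, H, W, N]   -- channel fastest
//   conv weights  w[Cin, k, k, Cout]
// With this layout a (Cout x Ho*Wo*N) GEMM result is directly the output
// array, and im2col rows line up with the flattened weight matrix, so the
// whole convolution is one BLAS call per direction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// col matrix: rows r = cin + Cin*(dh + k*dw), cols = ho + Ho*(wo + Wo*n)
static arma::mat im2col(const double* x, int C, int H, int W, int N,
                        int k, int s, int p, int Ho, int Wo) {
  arma::mat cols(C * k * k, (size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t c_idx = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double* col = cols.colptr(c_idx);
        for (int dw = 0; dw < k; ++dw) {
          int w = wo * s - p + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int h = ho * s - p + dh;
            if (h < 0 || h >= H) continue;
            const double* src = xn + (size_t)C * (h + (size_t)H * w);
            double* dst = col + (size_t)C * (dh + k * dw);
            std::copy(src, src + C, dst);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of a col matrix back onto the input grid (adjoint of im2col)
static void col2im_acc(const arma::mat& cols, double* gx,
                       int C, int H, int W, int N,
                       int k, int s, int p, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* gn = gx + (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t c_idx = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const double* col = cols.colptr(c_idx);
        for (int dw = 0; dw < k; ++dw) {
          int w = wo * s - p + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int h = ho * s - p + dh;
            if (h < 0 || h >= H) continue;
            double* dst = gn + (size_t)C * (h + (size_t)H * w);
            const double* src = col + (size_t)C * (dh + k * dw);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, int stride, int pad) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  int C = dx[0], H = dx[1], W = dx[2], N = dx[3];
  int Cin = dw[0], k = dw[1], Cout = dw[3];
  if (dw[2] != k) stop("non-square kernel");
  if (Cin != C) stop("channel mismatch in conv2d_forward");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");

  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)Cin * k * k, Cout, false, true);
  NumericVector y((size_t)Cout * Ho * Wo * N);
  arma::mat Y(REAL(y), Cout, (size_t)Ho * Wo * N, false, true);
  if (k == 1 && stride == 1 && pad == 0) {
    // pointwise conv: the input matrix is already the col matrix
    arma::mat X(const_cast<double*>(REAL(x)), C, (size_t)H * W * N, false, true);
    Y = Wm.t() * X;
  } else {
    arma::mat cols = im2col(REAL(x), C, H, W, N, k, stride, pad, Ho, Wo);
    Y = Wm.t() * cols;
  }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return y;
}

// gradient w.r.t. the conv input; also the forward pass of a transposed conv
// [[Rcpp::export]]
NumericVector conv2d_backward_data(NumericVector gy, NumericVector w,
                                   int stride, int pad, int H, int W) {
  int dg[4], dw[4];
  get_dims4(gy, dg); get_dims4(w, dw);
  int Cout = dg[0], Ho = dg[1], Wo = dg[2], N = dg[3];
  int Cin = dw[0], k = dw[1];
  if (dw[3] != Cout) stop("channel mismatch in conv2d_backward_data");

  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)Cin * k * k, Cout, false, true);
  arma::mat GY(const_cast<double*>(REAL(gy)), Cout, (size_t)Ho * Wo * N, false, true);

  NumericVector gx((size_t)Cin * H * W * N);  // zero-initialised
  if (k == 1 && stride == 1 && pad == 0 && Ho == H && Wo == W) {
    arma::mat GX(REAL(gx), Cin, (size_t)H * W * N, false, true);
    GX = Wm * GY;
  } else {
    arma::mat cols = Wm * GY;
    col2im_acc(cols, REAL(gx), Cin, H, W, N, k, stride, pad, Ho, Wo);
  }
  gx.attr("dim") = IntegerVector::create(Cin, H, W, N);
  return gx;
}

// gradient w.r.t. the conv weights
// [[Rcpp::export]]
NumericVector conv2d_backward_weight(NumericVector x, NumericVector gy,
                                     int k, int stride, int pad) {
  int dx[4], dg[4];
  get_dims4(x, dx); get_dims4(gy, dg);
  int C = dx[0], H = dx[1], W = dx[2], N = dx[3];
  int Cout = dg[0], Ho = dg[1], Wo = dg[2];
  if (dg[3] != N) stop("batch mismatch in conv2d_backward_weight");

  arma::mat GY(const_cast<double*>(REAL(gy)), Cout, (size_t)Ho * Wo * N, false, true);
  NumericVector gw((size_t)C * k * k * Cout);
  arma::mat GW(REAL(gw), (size_t)C * k * k, Cout, false, true);
  if (k == 1 && stride == 1 && pad == 0 && Ho == H && Wo == W) {
    arma::mat X(const_cast<double*>(REAL(x)), C, (size_t)H * W * N, false, true);
    GW = X * GY.t();
  } else {
    arma::mat cols = im2col(REAL(x), C, H, W, N, k, stride, pad, Ho, Wo);
    GW = cols * GY.t();
  }
  gw.attr("dim") = IntegerVector::create(C, k, k, Cout);
  return gw;
}

// sliding-window maximum with the window clipped at the borders; the
// max-pool (stride 1) step of the local-peak decoder
// [[Rcpp::export]]
NumericMatrix local_window_max(NumericMatrix hm, int window) {
  int H = hm.nrow(), W = hm.ncol();
  int r = window / 2;
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    int w0 = std::max(0, w - r), w1 = std::min(W - 1, w + r);
    for (int h = 0; h < H; ++h) {
      int h0 = std::max(0, h - r), h1 = std::min(H - 1, h + r);
      double m = R_NegInf;
      for (int ww = w0; ww <= w1; ++ww)
        for (int hh = h0; hh <= h1; ++hh)
          if (hm(hh, ww) > m) m = hm(hh, ww);
      out(h, w) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector relu_forward(NumericVector x) {
  NumericVector y(clone(x));
  double* p = REAL(y);
  R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_backward(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  const double* pg = REAL(g); const double* py = REAL(y);
  double* po = REAL(gx);
  R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = py[i] > 0 ? pg[i] : 0.0;
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// --- fused channel-wise helpers for batch normalisation -------------------
// all operate on [C, ...] arrays with the channel axis fastest

// per-channel mean and biased variance in one pass
// [[Rcpp::export]]
List channel_moments(NumericVector x, int C) {
  R_xlen_t n = x.size(); R_xlen_t m = n / C;
  NumericVector mu(C), va(C);
  const double* px = REAL(x);
  double* pm = REAL(mu); double* pv = REAL(va);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* col = px + (size_t)C * j;
    for (int c = 0; c < C; ++c) { pm[c] += col[c]; pv[c] += col[c] * col[c]; }
  }
  for (int c = 0; c < C; ++c) {
    pm[c] /= m;
    pv[c] = pv[c] / m - pm[c] * pm[c];
    if (pv[c] < 0) pv[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y[i] = x[i] * s[c] + t[c]
// [[Rcpp::export]]
NumericVector channel_affine(NumericVector x, NumericVector s, NumericVector t) {
  int C = s.size();
  R_xlen_t n = x.size(); R_xlen_t m = n / C;
  NumericVector y(n);
  const double* px = REAL(x); const double* ps = REAL(s); const double* pt = REAL(t);
  double* py = REAL(y);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xi = px + (size_t)C * j;
    double* yi = py + (size_t)C * j;
    for (int c = 0; c < C; ++c) yi[c] = xi[c] * ps[c] + pt[c];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// per-channel sum(g * xhat) and sum(g) in one pass
// [[Rcpp::export]]
List channel_dots(NumericVector g, NumericVector xhat, int C) {
  R_xlen_t n = g.size(); R_xlen_t m = n / C;
  NumericVector dg(C), db(C);
  const double* pg = REAL(g); const double* ph = REAL(xhat);
  double* pdg = REAL(dg); double* pdb = REAL(db);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* gi = pg + (size_t)C * j;
    const double* hi = ph + (size_t)C * j;
    for (int c = 0; c < C; ++c) { pdg[c] += gi[c] * hi[c]; pdb[c] += gi[c]; }
  }
  return List::create(_["dgamma"] = dg, _["dbeta"] = db);
}

// out[i] = a[i] * p[c] + b[i] * q[c] + r[c]
// [[Rcpp::export]]
NumericVector channel_affine2(NumericVector a, NumericVector b,
                              NumericVector p, NumericVector q, NumericVector r) {
  int C = p.size();
  R_xlen_t n = a.size(); R_xlen_t m = n / C;
  NumericVector y(n);
  const double* pa = REAL(a); const double* pb = REAL(b);
  const double* pp = REAL(p); const double* pq = REAL(q); const double* pr = REAL(r);
  double* py = REAL(y);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* ai = pa + (size_t)C * j;
    const double* bi = pb + (size_t)C * j;
    double* yi = py + (size_t)C * j;
    for (int c = 0; c < C; ++c) yi[c] = ai[c] * pp[c] + bi[c] * pq[c] + pr[c];
  }
  y.attr("dim") = a.attr("dim");
  return y;
}
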