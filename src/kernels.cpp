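// Compact CPU kernels for the clip-recognition training engine.
//
// Activation layout everywhere: a numeric matrix with H*W*N rows and C
// columns. Within one image, pixel (r, c) (0-based) sits at row r + c*H;
// the N images of a batch are stacked in blocks of H*W rows. Convolution
// weights are (kh*kw*Cin) x Cout with in-column order dr + dc*kh + ci*kh*kw.
//
// Arithmetic is float32 internally (gemm-bound); interfaces are double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int s, int k, int stride, int pad) {
  return (s + 2 * pad - k) / stride + 1;
}

static arma::fmat to_f(const NumericMatrix& m) {
  arma::fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

static arma::frowvec to_frow(const NumericVector& v) {
  arma::frowvec out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// im2col for one image: fills cols (HoWo x kh*kw*Cin), zero padding.
static void im2col(const arma::fmat& X, int H, int W, int n0,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::fmat& cols) {
  const int Cin = X.n_cols;
  cols.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = X.colptr(ci) + n0;
    for (int dc = 0; dc < kw; ++dc) {
      for (int dr = 0; dr < kh; ++dr) {
        const int col_idx = dr + dc * kh + ci * kh * kw;
        float* out = cols.colptr(col_idx);
        for (int co = 0; co < Wo; ++co) {
          const int c_in = co * stride - pad + dc;
          if (c_in < 0 || c_in >= W) continue;
          for (int ro = 0; ro < Ho; ++ro) {
            const int r_in = ro * stride - pad + dr;
            if (r_in < 0 || r_in >= H) continue;
            out[ro + co * Ho] = xc[r_in + c_in * H];
          }
        }
      }
    }
  }
}

// scatter-add of dcols back into dX for one image (col2im transpose).
static void col2im_add(const arma::fmat& dcols, int H, int W, int n0,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, arma::fmat& dX) {
  const int Cin = dX.n_cols;
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = dX.colptr(ci) + n0;
    for (int dc = 0; dc < kw; ++dc) {
      for (int dr = 0; dr < kh; ++dr) {
        const int col_idx = dr + dc * kh + ci * kh * kw;
        const float* src = dcols.colptr(col_idx);
        for (int co = 0; co < Wo; ++co) {
          const int c_in = co * stride - pad + dc;
          if (c_in < 0 || c_in >= W) continue;
          for (int ro = 0; ro < Ho; ++ro) {
            const int r_in = ro * stride - pad + dr;
            if (r_in < 0 || r_in >= H) continue;
            xc[r_in + c_in * H] += src[ro + co * Ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericMatrix conv2d_fw(const NumericMatrix& X_, int H, int W, int N,
                        const NumericMatrix& Wt_, const NumericVector& b_,
                        int kh, int kw, int stride, int pad) {
  const arma::fmat X = to_f(X_);
  const arma::fmat Wt = to_f(Wt_);
  const arma::frowvec b = to_frow(b_);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int Cout = Wt.n_cols;
  arma::fmat Y(Ho * Wo * N, Cout);
  arma::fmat cols(Ho * Wo, Wt.n_rows);
  for (int n = 0; n < N; ++n) {
    im2col(X, H, W, n * H * W, kh, kw, stride, pad, Ho, Wo, cols);
    Y.rows(n * Ho * Wo, (n + 1) * Ho * Wo - 1) = cols * Wt;
  }
  Y.each_row() += b;
  NumericMatrix out(Y.n_rows, Y.n_cols);
  std::copy(Y.begin(), Y.end(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const NumericMatrix& X_, int H, int W, int N,
               const NumericMatrix& Wt_, const NumericMatrix& dY_,
               int kh, int kw, int stride, int pad, bool need_dx) {
  const arma::fmat X = to_f(X_);
  const arma::fmat Wt = to_f(Wt_);
  const arma::fmat dY = to_f(dY_);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  arma::fmat dW(Wt.n_rows, Wt.n_cols, arma::fill::zeros);
  arma::fmat dX;
  if (need_dx) dX.zeros(X.n_rows, X.n_cols);
  arma::fmat cols(Ho * Wo, Wt.n_rows);
  for (int n = 0; n < N; ++n) {
    im2col(X, H, W, n * H * W, kh, kw, stride, pad, Ho, Wo, cols);
    const arma::fmat dYn = dY.rows(n * Ho * Wo, (n + 1) * Ho * Wo - 1);
    dW += cols.t() * dYn;
    if (need_dx) {
      const arma::fmat dcols = dYn * Wt.t();
      col2im_add(dcols, H, W, n * H * W, kh, kw, stride, pad, Ho, Wo, dX);
    }
  }
  const arma::frowvec db = arma::sum(dY, 0);
  NumericMatrix dWout(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(db.n_elem);
  std::copy(db.begin(), db.end(), dbout.begin());
  List res = List::create(_["dW"] = dWout, _["db"] = dbout);
  if (need_dx) {
    NumericMatrix dXout(dX.n_rows, dX.n_cols);
    std::copy(dX.begin(), dX.end(), dXout.begin());
    res["dX"] = dXout;
  }
  return res;
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(const NumericMatrix& X_, int H, int W, int N,
                int k, int stride, int pad) {
  const int C = X_.ncol();
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericMatrix Y(Ho * Wo * N, C);
  IntegerMatrix arg(Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X_(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + n * H * W;
      for (int co = 0; co < Wo; ++co) {
        for (int ro = 0; ro < Ho; ++ro) {
          double best = -std::numeric_limits<double>::infinity();
          int best_idx = -1;
          for (int dc = 0; dc < k; ++dc) {
            const int c_in = co * stride - pad + dc;
            if (c_in < 0 || c_in >= W) continue;
            for (int dr = 0; dr < k; ++dr) {
              const int r_in = ro * stride - pad + dr;
              if (r_in < 0 || r_in >= H) continue;
              const double v = xn[r_in + c_in * H];
              if (v > best) { best = v; best_idx = r_in + c_in * H; }
            }
          }
          const int orow = ro + co * Ho + n * Ho * Wo;
          Y(orow, c) = best;
          arg(orow, c) = best_idx + n * H * W + 1;  // 1-based global row
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericMatrix maxpool_bw(const NumericMatrix& dY_, const IntegerMatrix& arg,
                         int nrow_x) {
  const int C = dY_.ncol();
  const int n = dY_.nrow();
  NumericMatrix dX(nrow_x, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY_(0, c);
    const int* a = &arg(0, c);
    double* dx = &dX(0, c);
    for (int i = 0; i < n; ++i) dx[a[i] - 1] += dy[i];
  }
  return dX;
}

// Per-row max and argmax (channel-axis max pooling on the layout above).
// [[Rcpp::export(name = ".rowmax_fw")]]
List rowmax_fw(const NumericMatrix& X_) {
  const int n = X_.nrow(), C = X_.ncol();
  NumericVector val(n);
  IntegerVector arg(n);
  for (int i = 0; i < n; ++i) {
    double best = X_(i, 0);
    int bj = 0;
    for (int j = 1; j < C; ++j) {
      if (X_(i, j) > best) { best = X_(i, j); bj = j; }
    }
    val[i] = best;
    arg[i] = bj + 1;
  }
  return List::create(_["value"] = val, _["arg"] = arg);
}

// Fused batch-norm (+ optional ReLU) forward.
// train: per-column batch stats; returns Y, batch mean, ivar and the
// running-stat updates. eval: uses running stats.
// [[Rcpp::export(name = ".bn_fw")]]
List bn_fw(const NumericMatrix& X_, const NumericVector& gamma,
           const NumericVector& beta, const NumericVector& rm,
           const NumericVector& rv, double eps, double momentum,
           bool train, bool relu) {
  const int n = X_.nrow(), C = X_.ncol();
  NumericMatrix Y(n, C);
  NumericVector m(C), ivar(C), rm_new(C), rv_new(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X_(0, c);
    double* y = &Y(0, c);
    double mu, iv;
    if (train) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += x[i];
      mu = s / n;
      double v = 0;
      for (int i = 0; i < n; ++i) { const double d = x[i] - mu; v += d * d; }
      v /= n;
      iv = 1.0 / std::sqrt(v + eps);
      rm_new[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv_new[c] = (1 - momentum) * rv[c] + momentum * v * n / std::max(n - 1, 1);
    } else {
      mu = rm[c];
      iv = 1.0 / std::sqrt(rv[c] + eps);
    }
    m[c] = mu;
    ivar[c] = iv;
    const double a = gamma[c] * iv, b = beta[c] - mu * a;
    if (relu) {
      for (int i = 0; i < n; ++i) { const double v = a * x[i] + b; y[i] = v > 0 ? v : 0; }
    } else {
      for (int i = 0; i < n; ++i) y[i] = a * x[i] + b;
    }
  }
  List res = List::create(_["Y"] = Y, _["m"] = m, _["ivar"] = ivar);
  if (train) { res["rm"] = rm_new; res["rv"] = rv_new; }
  return res;
}

// Batch-norm (+ ReLU) backward; X is the conv output cached at forward,
// Yact the post-activation output (for the ReLU mask).
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(const NumericMatrix& X_, const NumericVector& m,
           const NumericVector& ivar, const NumericVector& gamma,
           const NumericMatrix& dY_, const NumericMatrix& Yact,
           bool relu) {
  const int n = X_.nrow(), C = X_.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X_(0, c);
    const double* dy = &dY_(0, c);
    const double* ya = relu ? &Yact(0, c) : nullptr;
    double* dx = &dX(0, c);
    const double mu = m[c], iv = ivar[c], g = gamma[c];
    double s1 = 0, s2 = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      const double d = (relu && ya[i] <= 0) ? 0 : dy[i];
      const double xh = (x[i] - mu) * iv;
      sb += d;
      s2 += d * xh;
      dx[i] = d;  // stash masked dY
    }
    dgamma[c] = s2;
    dbeta[c] = sb;
    s1 = sb * g;
    const double s2g = s2 * g;
    for (int i = 0; i < n; ++i) {
      const double xh = (x[i] - mu) * iv;
      dx[i] = (dx[i] * g - s1 / n - xh * s2g / n) * iv;
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
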