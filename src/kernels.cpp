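// Low-level kernels for the convolutional engine and the polygon rasterizer.
//
// Activation layout convention (shared with the R side): a batched feature
// map of N samples, height H, width W, C channels is a numeric matrix of
// dimension (N*H*W) x C, with row index r = n*H*W + i*W + j (i = row,
// j = column, all 0-based). Channels are columns so GEMMs against weight
// matrices of shape (C*k*k) x Cout run through BLAS on the R side.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pad, int dil) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int N, int H, int W,
                         int k, int stride, int pad, int dil) {
  const int C = x.ncol();
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const R_xlen_t xrows = (R_xlen_t)N * H * W;
  const R_xlen_t crows = (R_xlen_t)N * Ho * Wo;
  NumericMatrix cols(crows, C * k * k);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * xrows;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int cc = c * k * k + ki * k + kj;
        double* col = cp + (R_xlen_t)cc * crows;
        const int joff = kj * dil - pad;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (R_xlen_t)n * H * W;
          double* cn = col + (R_xlen_t)n * Ho * Wo;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - pad + ki * dil;
            double* crow = cn + (R_xlen_t)oi * Wo;
            if (ii < 0 || ii >= H) continue;
            const double* xrow = xn + (R_xlen_t)ii * W;
            // valid oj: 0 <= oj*stride + joff < W
            int lo = (joff < 0) ? (-joff + stride - 1) / stride : 0;
            int hi = (W - 1 - joff) / stride;
            if (hi > Wo - 1) hi = Wo - 1;
            if (stride == 1) {
              for (int oj = lo; oj <= hi; ++oj) crow[oj] = xrow[oj + joff];
            } else {
              for (int oj = lo; oj <= hi; ++oj)
                crow[oj] = xrow[oj * stride + joff];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int N, int H, int W,
                         int C, int k, int stride, int pad, int dil) {
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const R_xlen_t xrows = (R_xlen_t)N * H * W;
  const R_xlen_t crows = (R_xlen_t)N * Ho * Wo;
  NumericMatrix x(xrows, C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (R_xlen_t)c * xrows;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int cc = c * k * k + ki * k + kj;
        const double* col = cp + (R_xlen_t)cc * crows;
        const int joff = kj * dil - pad;
        for (int n = 0; n < N; ++n) {
          double* xn = xc + (R_xlen_t)n * H * W;
          const double* cn = col + (R_xlen_t)n * Ho * Wo;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            double* xrow = xn + (R_xlen_t)ii * W;
            const double* crow = cn + (R_xlen_t)oi * Wo;
            int lo = (joff < 0) ? (-joff + stride - 1) / stride : 0;
            int hi = (W - 1 - joff) / stride;
            if (hi > Wo - 1) hi = Wo - 1;
            if (stride == 1) {
              for (int oj = lo; oj <= hi; ++oj) xrow[oj + joff] += crow[oj];
            } else {
              for (int oj = lo; oj <= hi; ++oj)
                xrow[oj * stride + joff] += crow[oj];
            }
          }
        }
      }
    }
  }
  return x;
}

// im2col for one sample into a caller-provided column-major buffer of
// dimension (Ho*Wo) x (C*k*k); rows of x for this sample start at xs.
static void im2col_sample(const double* xs, R_xlen_t xstride, int C,
                          int H, int W, int k, int stride, int pad, int dil,
                          int Ho, int Wo, double* buf) {
  const R_xlen_t brows = (R_xlen_t)Ho * Wo;
  std::fill(buf, buf + brows * C * k * k, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (R_xlen_t)c * xstride;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        double* col = buf + ((R_xlen_t)(c * k * k + ki * k + kj)) * brows;
        const int joff = kj * dil - pad;
        for (int oi = 0; oi < Ho; ++oi) {
          const int ii = oi * stride - pad + ki * dil;
          if (ii < 0 || ii >= H) continue;
          const double* xrow = xc + (R_xlen_t)ii * W;
          double* crow = col + (R_xlen_t)oi * Wo;
          int lo = (joff < 0) ? (-joff + stride - 1) / stride : 0;
          int hi = (W - 1 - joff) / stride;
          if (hi > Wo - 1) hi = Wo - 1;
          for (int oj = lo; oj <= hi; ++oj)
            crow[oj] = xrow[oj * stride + joff];
        }
      }
    }
  }
}

static void col2im_sample(const double* buf, double* xs, R_xlen_t xstride,
                          int C, int H, int W, int k, int stride, int pad,
                          int dil, int Ho, int Wo) {
  const R_xlen_t brows = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* xc = xs + (R_xlen_t)c * xstride;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const double* col = buf + ((R_xlen_t)(c * k * k + ki * k + kj)) * brows;
        const int joff = kj * dil - pad;
        for (int oi = 0; oi < Ho; ++oi) {
          const int ii = oi * stride - pad + ki * dil;
          if (ii < 0 || ii >= H) continue;
          double* xrow = xc + (R_xlen_t)ii * W;
          const double* crow = col + (R_xlen_t)oi * Wo;
          int lo = (joff < 0) ? (-joff + stride - 1) / stride : 0;
          int hi = (W - 1 - joff) / stride;
          if (hi > Wo - 1) hi = Wo - 1;
          for (int oj = lo; oj <= hi; ++oj)
            xrow[oj * stride + joff] += crow[oj];
        }
      }
    }
  }
}

// Fused convolution forward: per-sample im2col into a reusable buffer plus
// dgemm into the strided output block. x: (N*H*W) x C, w: (C*k*k) x Cout.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fw(const NumericMatrix& x, int N, int H, int W,
                          const NumericMatrix& w, int k, int stride, int pad,
                          int dil) {
  const int C = x.ncol();
  const int Cout = w.ncol();
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int K = C * k * k;
  const R_xlen_t yrows = (R_xlen_t)N * Ho * Wo;
  const R_xlen_t xrows = (R_xlen_t)N * H * W;
  NumericMatrix y(yrows, Cout);
  std::vector<double> buf((R_xlen_t)Ho * Wo * K);
  const int M = Ho * Wo;
  const double one = 1.0, zero = 0.0;
  const int ldy = (int)yrows;
  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin() + (R_xlen_t)n * H * W, xrows, C, H, W, k,
                  stride, pad, dil, Ho, Wo, buf.data());
    F77_CALL(dgemm)("N", "N", &M, &Cout, &K, &one, buf.data(), &M,
                    w.begin(), &K, &zero,
                    y.begin() + (R_xlen_t)n * Ho * Wo, &ldy
                    FCONE FCONE);
  }
  return y;
}

// Fused convolution backward: returns dx and dw.
// dy: (N*Ho*Wo) x Cout.
// [[Rcpp::export]]
List cpp_conv_bw(const NumericMatrix& dy, const NumericMatrix& x,
                 int N, int H, int W, const NumericMatrix& w, int k,
                 int stride, int pad, int dil) {
  const int C = x.ncol();
  const int Cout = w.ncol();
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int K = C * k * k;
  const R_xlen_t yrows = (R_xlen_t)N * Ho * Wo;
  const R_xlen_t xrows = (R_xlen_t)N * H * W;
  NumericMatrix dx(xrows, C);
  NumericMatrix dw(K, Cout);
  std::vector<double> buf((R_xlen_t)Ho * Wo * K);
  const int M = Ho * Wo;
  const double one = 1.0, zero = 0.0;
  const int ldy = (int)yrows;
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (R_xlen_t)n * Ho * Wo;
    // dw += cols(n)^T %*% dy(n): rebuild cols for the sample
    im2col_sample(x.begin() + (R_xlen_t)n * H * W, xrows, C, H, W, k,
                  stride, pad, dil, Ho, Wo, buf.data());
    F77_CALL(dgemm)("T", "N", &K, &Cout, &M, &one, buf.data(), &M,
                    dyn, &ldy, &one, dw.begin(), &K FCONE FCONE);
    // dcols = dy(n) %*% w^T, scattered back into dx
    F77_CALL(dgemm)("N", "T", &M, &K, &Cout, &one, dyn, &ldy,
                    w.begin(), &K, &zero, buf.data(), &M FCONE FCONE);
    col2im_sample(buf.data(), dx.begin() + (R_xlen_t)n * H * W, xrows, C,
                  H, W, k, stride, pad, dil, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// one-pass per-column mean and (biased) variance
// [[Rcpp::export]]
List cpp_colstats(const NumericMatrix& x) {
  const R_xlen_t n = x.nrow();
  const int C = x.ncol();
  NumericVector mu(C), v(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * n;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    mu[c] = m;
    double var = s2 / n - m * m;
    v[c] = var > 0 ? var : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// column-wise affine map y[, c] = x[, c] * a[c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_colscale_shift(const NumericMatrix& x,
                                 const NumericVector& a,
                                 const NumericVector& b) {
  const R_xlen_t n = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(n, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = xp + (R_xlen_t)c * n;
    double* yc = yp + (R_xlen_t)c * n;
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = xc[i] * ac + bc;
  }
  return y;
}

// y[, c] = x1[, c] * a1[c] + x2[, c] * a2[c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_axpby_cols(const NumericMatrix& x1, const NumericVector& a1,
                             const NumericMatrix& x2, const NumericVector& a2,
                             const NumericVector& b) {
  const R_xlen_t n = x1.nrow();
  const int C = x1.ncol();
  NumericMatrix y(n, C);
  const double* p1 = x1.begin();
  const double* p2 = x2.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double s1 = a1[c], s2 = a2[c], bc = b[c];
    const double* c1 = p1 + (R_xlen_t)c * n;
    const double* c2 = p2 + (R_xlen_t)c * n;
    double* yc = yp + (R_xlen_t)c * n;
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = c1[i] * s1 + c2[i] * s2 + bc;
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_fw(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_bw(const NumericMatrix& dy, const NumericMatrix& x) {
  NumericMatrix g(dy.nrow(), dy.ncol());
  const double* dp = dy.begin();
  const double* xp = x.begin();
  double* gp = g.begin();
  const R_xlen_t n = (R_xlen_t)dy.nrow() * dy.ncol();
  for (R_xlen_t i = 0; i < n; ++i) gp[i] = xp[i] > 0 ? dp[i] : 0;
  return g;
}

// Depthwise kxk convolution, "same"-style padding pad = dil*(k-1)/2, with
// optional stride. w is (k*k) x C.
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_fw(const NumericMatrix& x, int N, int H, int W,
                            const NumericMatrix& w, int dil, int stride) {
  const int C = x.ncol();
  const int k = (int)std::lround(std::sqrt((double)w.nrow()));
  const int pad = dil * (k - 1) / 2;
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  NumericMatrix y((double)N * Ho * Wo, C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const R_xlen_t xrows = (R_xlen_t)N * H * W;
  const R_xlen_t yrows = (R_xlen_t)N * Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * xrows;
    const double* wc = wp + (R_xlen_t)c * k * k;
    double* yc = yp + (R_xlen_t)c * yrows;
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (R_xlen_t)n * H * W;
      double* yn = yc + (R_xlen_t)n * Ho * Wo;
      for (int oi = 0; oi < Ho; ++oi) {
        double* yrow = yn + (R_xlen_t)oi * Wo;
        for (int ki = 0; ki < k; ++ki) {
          const int ii = oi * stride - pad + ki * dil;
          if (ii < 0 || ii >= H) continue;
          const double* xrow = xn + (R_xlen_t)ii * W;
          for (int kj = 0; kj < k; ++kj) {
            const int joff = kj * dil - pad;
            const double wv = wc[ki * k + kj];
            int lo = (joff < 0) ? (-joff + stride - 1) / stride : 0;
            int hi = (W - 1 - joff) / stride;
            if (hi > Wo - 1) hi = Wo - 1;
            for (int oj = lo; oj <= hi; ++oj)
              yrow[oj] += wv * xrow[oj * stride + joff];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(const NumericMatrix& dy, const NumericMatrix& x,
                   int N, int H, int W, const NumericMatrix& w, int dil,
                   int stride) {
  const int C = x.ncol();
  const int k = (int)std::lround(std::sqrt((double)w.nrow()));
  const int pad = dil * (k - 1) / 2;
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  NumericMatrix dx((double)N * H * W, C);
  NumericMatrix dw(k * k, C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const R_xlen_t xrows = (R_xlen_t)N * H * W;
  const R_xlen_t yrows = (R_xlen_t)N * Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * xrows;
    const double* wc = wp + (R_xlen_t)c * k * k;
    const double* gc = gp + (R_xlen_t)c * yrows;
    double* dxc = dxp + (R_xlen_t)c * xrows;
    double* dwc = dwp + (R_xlen_t)c * k * k;
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (R_xlen_t)n * H * W;
      const double* gn = gc + (R_xlen_t)n * Ho * Wo;
      double* dxn = dxc + (R_xlen_t)n * H * W;
      for (int oi = 0; oi < Ho; ++oi) {
        const double* grow = gn + (R_xlen_t)oi * Wo;
        for (int ki = 0; ki < k; ++ki) {
          const int ii = oi * stride - pad + ki * dil;
          if (ii < 0 || ii >= H) continue;
          const double* xrow = xn + (R_xlen_t)ii * W;
          double* dxrow = dxn + (R_xlen_t)ii * W;
          for (int kj = 0; kj < k; ++kj) {
            const int joff = kj * dil - pad;
            const double wv = wc[ki * k + kj];
            double acc = 0.0;
            int lo = (joff < 0) ? (-joff + stride - 1) / stride : 0;
            int hi = (W - 1 - joff) / stride;
            if (hi > Wo - 1) hi = Wo - 1;
            for (int oj = lo; oj <= hi; ++oj) {
              const double g = grow[oj];
              dxrow[oj * stride + joff] += g * wv;
              acc += g * xrow[oj * stride + joff];
            }
            dwc[ki * k + kj] += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// fused batch-norm affine + ReLU: y = max(x * a[c] + b[c], 0)
// [[Rcpp::export]]
NumericMatrix cpp_affine_relu_fw(const NumericMatrix& x,
                                 const NumericVector& a,
                                 const NumericVector& b) {
  const R_xlen_t n = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(n, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = xp + (R_xlen_t)c * n;
    double* yc = yp + (R_xlen_t)c * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = xc[i] * ac + bc;
      yc[i] = v > 0 ? v : 0;
    }
  }
  return y;
}

// backward of the fused op w.r.t. its pre-affine input: pass dy where the
// fused output was positive, scaled by a[c]; also return the per-channel
// sums needed for the affine parameters' gradients.
// [[Rcpp::export]]
List cpp_affine_relu_bw(const NumericMatrix& dy, const NumericMatrix& y,
                        const NumericVector& a) {
  const R_xlen_t n = dy.nrow();
  const int C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector sum_dy(C), sum_dy_y(C);
  const double* dp = dy.begin();
  const double* yp = y.begin();
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double* dc = dp + (R_xlen_t)c * n;
    const double* yc = yp + (R_xlen_t)c * n;
    double* xc = xp + (R_xlen_t)c * n;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (yc[i] > 0) {
        const double g = dc[i];
        xc[i] = g * ac;
        s1 += g;
        s2 += g * yc[i];
      }
    }
    sum_dy[c] = s1;
    sum_dy_y[c] = s2;
  }
  return List::create(_["dx"] = dx, _["sum_dy"] = sum_dy,
                      _["sum_dy_y"] = sum_dy_y);
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping): the GEMM
// x %*% W with W of shape C x (4*Cout) is done in R; here we scatter the
// (N*H*W) x (4*Cout) product into the upsampled (N*2H*2W) x Cout layout.
// Column index of m: (a*2 + b)*Cout + co, output pixel (2i+a, 2j+b).
// [[Rcpp::export]]
NumericMatrix cpp_tconv2_scatter(const NumericMatrix& m, int N, int H, int W,
                                 int Cout) {
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix y((double)N * H2 * W2, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int a = 0; a < 2; ++a) {
      for (int b = 0; b < 2; ++b) {
        const int mc = (a * 2 + b) * Cout + co;
        for (int n = 0; n < N; ++n) {
          const int moff = n * H * W, yoff = n * H2 * W2;
          for (int i = 0; i < H; ++i) {
            for (int j = 0; j < W; ++j) {
              y(yoff + (2 * i + a) * W2 + (2 * j + b), co) =
                m(moff + i * W + j, mc);
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_tconv2_gather(const NumericMatrix& dy, int N, int H, int W,
                                int Cout) {
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix dm((double)N * H * W, 4 * Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int a = 0; a < 2; ++a) {
      for (int b = 0; b < 2; ++b) {
        const int mc = (a * 2 + b) * Cout + co;
        for (int n = 0; n < N; ++n) {
          const int moff = n * H * W, yoff = n * H2 * W2;
          for (int i = 0; i < H; ++i) {
            for (int j = 0; j < W; ++j) {
              dm(moff + i * W + j, mc) =
                dy(yoff + (2 * i + a) * W2 + (2 * j + b), co);
            }
          }
        }
      }
    }
  }
  return dm;
}

// Bilinear resize, half-pixel-center mapping, clamped at borders.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear_fw(const NumericMatrix& x, int N, int H,
                                     int W, int Ho, int Wo) {
  const int C = x.ncol();
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  NumericMatrix y((double)N * Ho * Wo, C);
  for (int oi = 0; oi < Ho; ++oi) {
    double si = (oi + 0.5) * sh - 0.5;
    if (si < 0) si = 0; if (si > H - 1) si = H - 1;
    const int i0 = (int)std::floor(si), i1 = (i0 + 1 < H) ? i0 + 1 : i0;
    const double wi = si - i0;
    for (int oj = 0; oj < Wo; ++oj) {
      double sj = (oj + 0.5) * sw - 0.5;
      if (sj < 0) sj = 0; if (sj > W - 1) sj = W - 1;
      const int j0 = (int)std::floor(sj), j1 = (j0 + 1 < W) ? j0 + 1 : j0;
      const double wj = sj - j0;
      for (int n = 0; n < N; ++n) {
        const int xoff = n * H * W, yoff = n * Ho * Wo;
        for (int c = 0; c < C; ++c) {
          const double v =
            (1 - wi) * ((1 - wj) * x(xoff + i0 * W + j0, c) +
                        wj * x(xoff + i0 * W + j1, c)) +
            wi * ((1 - wj) * x(xoff + i1 * W + j0, c) +
                  wj * x(xoff + i1 * W + j1, c));
          y(yoff + oi * Wo + oj, c) = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear_bw(const NumericMatrix& dy, int N, int H,
                                     int W, int Ho, int Wo) {
  const int C = dy.ncol();
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  NumericMatrix dx((double)N * H * W, C);
  for (int oi = 0; oi < Ho; ++oi) {
    double si = (oi + 0.5) * sh - 0.5;
    if (si < 0) si = 0; if (si > H - 1) si = H - 1;
    const int i0 = (int)std::floor(si), i1 = (i0 + 1 < H) ? i0 + 1 : i0;
    const double wi = si - i0;
    for (int oj = 0; oj < Wo; ++oj) {
      double sj = (oj + 0.5) * sw - 0.5;
      if (sj < 0) sj = 0; if (sj > W - 1) sj = W - 1;
      const int j0 = (int)std::floor(sj), j1 = (j0 + 1 < W) ? j0 + 1 : j0;
      const double wj = sj - j0;
      for (int n = 0; n < N; ++n) {
        const int xoff = n * H * W, yoff = n * Ho * Wo;
        for (int c = 0; c < C; ++c) {
          const double g = dy(yoff + oi * Wo + oj, c);
          dx(xoff + i0 * W + j0, c) += g * (1 - wi) * (1 - wj);
          dx(xoff + i0 * W + j1, c) += g * (1 - wi) * wj;
          dx(xoff + i1 * W + j0, c) += g * wi * (1 - wj);
          dx(xoff + i1 * W + j1, c) += g * wi * wj;
        }
      }
    }
  }
  return dx;
}

// Backward warp of a single-channel H x W image by target-pixel source maps
// (map_r, map_c give, for every output pixel, the source row/col, 0-based).
// Out-of-bounds samples read as `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& img,
                                const NumericMatrix& map_r,
                                const NumericMatrix& map_c, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const double si = map_r(i, j), sj = map_c(i, j);
      const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      const double wi = si - i0, wj = sj - j0;
      double acc = 0.0;
      for (int a = 0; a <= 1; ++a) {
        for (int b = 0; b <= 1; ++b) {
          const int ii = i0 + a, jj = j0 + b;
          const double wgt = (a ? wi : 1 - wi) * (b ? wj : 1 - wj);
          const double v = (ii >= 0 && ii < H && jj >= 0 && jj < W)
            ? img(ii, jj) : fill;
          acc += wgt * v;
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_nearest(const NumericMatrix& img,
                               const NumericMatrix& map_r,
                               const NumericMatrix& map_c, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const int ii = (int)std::lround(map_r(i, j));
      const int jj = (int)std::lround(map_c(i, j));
      out(i, j) = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? img(ii, jj) : fill;
    }
  }
  return out;
}

// Even-odd scanline polygon fill over pixel centers, plus Bresenham edge
// marking so pixels whose center lies on a polygon edge count as foreground.
// Vertices are rounded to the nearest integer first; coordinates are
// LabelMe-style (x = column, y = row, 0-based). Shapes merge by union.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_polygons(int height, int width, List polys) {
  IntegerMatrix mask(height, width);
  const int nshape = polys.size();
  for (int s = 0; s < nshape; ++s) {
    NumericMatrix p = polys[s];
    const int nv = p.nrow();
    if (nv < 3) continue;
    std::vector<double> px(nv), py(nv);
    for (int v = 0; v < nv; ++v) {
      px[v] = std::round(p(v, 0));
      py[v] = std::round(p(v, 1));
    }
    // interior: even-odd crossings of a +x ray from each pixel center
    for (int i = 0; i < height; ++i) {
      std::vector<double> xs;
      for (int v = 0; v < nv; ++v) {
        const int u = (v + 1) % nv;
        const double y1 = py[v], y2 = py[u];
        if ((y1 > i) != (y2 > i)) {
          xs.push_back(px[v] + (i - y1) * (px[u] - px[v]) / (y2 - y1));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t m = 0; m + 1 < xs.size(); m += 2) {
        int j0 = (int)std::ceil(xs[m]);
        int j1 = (int)std::floor(xs[m + 1]);
        if (j0 < 0) j0 = 0;
        if (j1 > width - 1) j1 = width - 1;
        for (int j = j0; j <= j1; ++j) mask(i, j) = 1;
      }
    }
    // boundary: pixel centers lying exactly on an edge (lattice points of
    // the segment between the integer-rounded vertices)
    for (int v = 0; v < nv; ++v) {
      const int u = (v + 1) % nv;
      const int x0 = (int)px[v], y0 = (int)py[v];
      const int x1 = (int)px[u], y1 = (int)py[u];
      const int dx = x1 - x0, dy = y1 - y0;
      int g = std::abs(dx) > std::abs(dy) ? std::abs(dx) : std::abs(dy);
      {
        int a = std::abs(dx), b = std::abs(dy);
        while (b != 0) { const int t = a % b; a = b; b = t; }
        g = a > 0 ? a : 1;
      }
      for (int t = 0; t <= g; ++t) {
        const int xi = x0 + t * dx / g, yi = y0 + t * dy / g;
        if (yi >= 0 && yi < height && xi >= 0 && xi < width) mask(yi, xi) = 1;
      }
    }
  }
  return mask;
}

// Directed/undirected Hausdorff distance between two point sets given as
// m x 2 matrices of (row, col) coordinates.
// [[Rcpp::export]]
double cpp_hausdorff(const NumericMatrix& A, const NumericMatrix& B) {
  const int na = A.nrow(), nb = B.nrow();
  double hab = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dr = A(i, 0) - B(j, 0), dc = A(i, 1) - B(j, 1);
      const double d = dr * dr + dc * dc;
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    if (best > hab) hab = best;
  }
  double hba = 0.0;
  for (int j = 0; j < nb; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double dr = A(i, 0) - B(j, 0), dc = A(i, 1) - B(j, 1);
      const double d = dr * dr + dc * dc;
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    if (best > hba) hba = best;
  }
  return std::sqrt(hab > hba ? hab : hba);
}
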