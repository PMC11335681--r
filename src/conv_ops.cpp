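#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored R-side as arrays with dim c(H, W, C) (column-major),
// so x[h, w, c] lives at index h + H*w + H*W*c (0-based).
//
// im2col unrolls every kernel window into one column of a (C*kh*kw) x
// (Hout*Wout) matrix; convolution is then a single GEMM done in R via BLAS.
// Row ordering within a column: r = c*kh*kw + i*kw + j for kernel offset
// (i, j) in channel c. Column ordering: l = ho + Hout*wo. Stride is 1
// throughout (pooling is a separate op); `dil` is the dilation rate and
// `pad` the zero padding on every side.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int pad, int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  if (Hout < 1 || Wout < 1)
    stop("im2col: output size would be non-positive (input %d x %d)", H, W);
  const int L = Hout * Wout;
  const int R = C * kh * kw;
  NumericMatrix cols(R, L);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const int l = ho + Hout * wo;
      double* col = cp + (size_t)l * R;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)c * H * W;
        for (int i = 0; i < kh; ++i) {
          const int h = ho + dil * i - pad;
          const bool hin = (h >= 0 && h < H);
          for (int j = 0; j < kw; ++j) {
            const int w = wo + dil * j - pad;
            double v = 0.0;
            if (hin && w >= 0 && w < W) v = xc[h + (size_t)H * w];
            col[c * kh * kw + i * kw + j] = v;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back onto the (H, W, C) grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int pad, int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  const int R = C * kh * kw;
  NumericVector x(H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const int l = ho + Hout * wo;
      const double* col = cp + (size_t)l * R;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + (size_t)c * H * W;
        for (int i = 0; i < kh; ++i) {
          const int h = ho + dil * i - pad;
          if (h < 0 || h >= H) continue;
          for (int j = 0; j < kw; ++j) {
            const int w = wo + dil * j - pad;
            if (w < 0 || w >= W) continue;
            xc[h + (size_t)H * w] += col[c * kh * kw + i * kw + j];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Transposed-layout im2col: returns an (Hout*Wout) x (C*kh*kw) matrix whose
// column r = c*kh*kw + i*kw + j holds the (i, j) kernel tap of channel c for
// every output position (rows ordered l = ho + Hout*wo). Both reads and
// writes run nearly sequentially in h, which is considerably more
// cache-friendly than the (R x L) layout, and the convolution GEMM
// cols %*% t(W) then yields the output in array layout with no transpose.

// [[Rcpp::export]]
NumericMatrix im2colT_cpp(NumericVector x, int H, int W, int C,
                          int kh, int kw, int pad, int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  if (Hout < 1 || Wout < 1)
    stop("im2col: output size would be non-positive (input %d x %d)", H, W);
  const int L = Hout * Wout;
  NumericMatrix cols(L, C * kh * kw);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        double* col = cp + (size_t)(c * kh * kw + i * kw + j) * L;
        for (int wo = 0; wo < Wout; ++wo) {
          const int w = wo + dil * j - pad;
          double* dst = col + (size_t)Hout * wo;
          if (w < 0 || w >= W) {
            for (int ho = 0; ho < Hout; ++ho) dst[ho] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * w;
          for (int ho = 0; ho < Hout; ++ho) {
            const int h = ho + dil * i - pad;
            dst[ho] = (h >= 0 && h < H) ? src[h] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2colT_cpp.

// [[Rcpp::export]]
NumericVector col2imT_cpp(NumericMatrix cols, int H, int W, int C,
                          int kh, int kw, int pad, int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  NumericVector x(H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const int L = Hout * Wout;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * H * W;
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        const double* col = cp + (size_t)(c * kh * kw + i * kw + j) * L;
        for (int wo = 0; wo < Wout; ++wo) {
          const int w = wo + dil * j - pad;
          if (w < 0 || w >= W) continue;
          double* dst = xc + (size_t)H * w;
          const double* src = col + (size_t)Hout * wo;
          for (int ho = 0; ho < Hout; ++ho) {
            const int h = ho + dil * i - pad;
            if (h >= 0 && h < H) dst[h] += src[ho];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// One fused SGD-with-momentum update:
//   v <- momentum*v + grad + wd*value;  value <- value - lr*v
// Returns the updated (value, velocity) pair in a single pass, avoiding the
// intermediate allocations of the equivalent R arithmetic.

// [[Rcpp::export]]
List sgd_update_cpp(NumericVector value, NumericVector grad,
                    NumericVector vel, double lr, double momentum,
                    double wd) {
  const int n = value.size();
  NumericVector v2(n), val2(n);
  const bool has_vel = vel.size() == n;
  for (int i = 0; i < n; ++i) {
    double v = (has_vel ? momentum * vel[i] : 0.0) + grad[i] + wd * value[i];
    v2[i] = v;
    val2[i] = value[i] - lr * v;
  }
  val2.attr("dim") = value.attr("dim");
  return List::create(_["value"] = val2, _["vel"] = v2);
}

// In-place fused SGD update over a pre-allocated velocity buffer. The
// engine guarantees no live aliases of parameter/velocity arrays exist
// between optimizer steps, so mutating them avoids ~2 full-size
// allocations per parameter per step.

// [[Rcpp::export]]
void sgd_update_inplace_cpp(NumericVector value, NumericVector grad,
                            NumericVector vel, double lr, double momentum,
                            double wd) {
  const int n = value.size();
  double* val = value.begin();
  const double* g = grad.begin();
  double* v = vel.begin();
  for (int i = 0; i < n; ++i) {
    const double vi = momentum * v[i] + g[i] + wd * val[i];
    v[i] = vi;
    val[i] -= lr * vi;
  }
}

// Per-channel batch normalization over the spatial extent (biased variance):
// forward returns y plus the cached normalized activations and per-channel
// inverse standard deviations needed by backward.

// [[Rcpp::export]]
List batchnorm_fwd_cpp(NumericVector x, int N, int C, NumericVector gamma,
                       NumericVector beta, double eps) {
  NumericVector y(N * C), xhat(N * C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * N;
    double* yc = y.begin() + (size_t)c * N;
    double* hc = xhat.begin() + (size_t)c * N;
    double mu = 0.0;
    for (int i = 0; i < N; ++i) mu += xc[i];
    mu /= N;
    double var = 0.0;
    for (int i = 0; i < N; ++i) { const double d = xc[i] - mu; var += d * d; }
    var /= N;
    const double isd = 1.0 / std::sqrt(var + eps);
    inv_sd[c] = isd;
    const double gc = gamma[c], bc = beta[c];
    for (int i = 0; i < N; ++i) {
      const double h = (xc[i] - mu) * isd;
      hc[i] = h;
      yc[i] = gc * h + bc;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List batchnorm_bwd_cpp(NumericVector g, NumericVector xhat,
                       NumericVector inv_sd, NumericVector gamma,
                       int N, int C) {
  NumericVector dx(N * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* gc = g.begin() + (size_t)c * N;
    const double* hc = xhat.begin() + (size_t)c * N;
    double* dxc = dx.begin() + (size_t)c * N;
    double s1 = 0.0, s2 = 0.0, dg = 0.0, db = 0.0;
    for (int i = 0; i < N; ++i) {
      const double gm = gc[i] * gamma[c];
      s1 += gm;
      s2 += gm * hc[i];
      dg += gc[i] * hc[i];
      db += gc[i];
    }
    dgamma[c] = dg;
    dbeta[c] = db;
    const double m1 = s1 / N, m2 = s2 / N, isd = inv_sd[c], ga = gamma[c];
    for (int i = 0; i < N; ++i)
      dxc[i] = (gc[i] * ga - m1 - hc[i] * m2) * isd;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Box-mean filter with zero padding, dividing by the full kernel area
// (framework-style average pooling with stride 1 and padding k/2); used for
// the boundary-emphasis weight map of the weighted losses. No gradient is
// needed: it only ever runs on ground-truth masks.

// [[Rcpp::export]]
NumericMatrix box_mean_cpp(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol();
  const int pad = k / 2;
  NumericMatrix out(H, W);
  const double area = (double)k * k;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double s = 0.0;
      for (int dw = -pad; dw <= k - 1 - pad; ++dw) {
        const int ww = w + dw;
        if (ww < 0 || ww >= W) continue;
        for (int dh = -pad; dh <= k - 1 - pad; ++dh) {
          const int hh = h + dh;
          if (hh < 0 || hh >= H) continue;
          s += x(hh, ww);
        }
      }
      out(h, w) = s / area;
    }
  }
  return out;
}
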