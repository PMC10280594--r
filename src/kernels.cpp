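// Native tensor kernels for the multitask detector/segmenter.
//
// Feature maps are R arrays with dim(H, W, C, N): each channel plane is a
// contiguous H x W column-major block, so an arma::cube(H, W, C) can alias
// one sample without copying. Dense convolutions go through im2col + GEMM;
// depthwise convolutions (the Ghost 5x5 "cheap operation" and the stride-2
// downsampling paths) use a direct loop. Every forward kernel has a matching
// backward kernel; the graph executor in R chains them in reverse
// topological order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C,
                             int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline NumericVector make4(int H, int W, int C, int N) {
  NumericVector y(static_cast<R_xlen_t>(H) * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// ---------------------------------------------------------------------------
// im2col: column q = oi + Ho*oj holds the receptive field of output pixel
// (oi, oj); row r = (c*k + ki)*k + kj. Out-of-bounds taps are zero.
static void im2col(const double *x, int H, int W, int C, int k, int s, int p,
                   int Ho, int Wo, arma::mat &cols) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + static_cast<size_t>(c) * H * W;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        int r = (c * k + ki) * k + kj;
        double *dst = cols.memptr() + static_cast<size_t>(r);
        const int nr = cols.n_rows;
        for (int oj = 0; oj < Wo; ++oj) {
          int wj = oj * s - p + kj;
          for (int oi = 0; oi < Ho; ++oi) {
            int wi = oi * s - p + ki;
            double v = 0.0;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              v = xc[static_cast<size_t>(wj) * H + wi];
            dst[static_cast<size_t>(oj * Ho + oi) * nr] = v;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &cols, int H, int W, int C, int k, int s,
                   int p, int Ho, int Wo, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + static_cast<size_t>(c) * H * W;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        int r = (c * k + ki) * k + kj;
        const double *src = cols.memptr() + static_cast<size_t>(r);
        const int nr = cols.n_rows;
        for (int oj = 0; oj < Wo; ++oj) {
          int wj = oj * s - p + kj;
          if (wj < 0 || wj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int wi = oi * s - p + ki;
            if (wi < 0 || wi >= H) continue;
            xc[static_cast<size_t>(wj) * H + wi] +=
                src[static_cast<size_t>(oj * Ho + oi) * nr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix w,
                            Nullable<NumericVector> bias, int k, int stride,
                            int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (w.nrow() != k * k * C) stop("weight rows != k*k*C");
  int c2 = w.ncol();
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y = make4(Ho, Wo, c2, N);
  arma::mat wm(w.begin(), w.nrow(), c2, false);
  arma::mat cols(static_cast<size_t>(k) * k * C,
                 static_cast<size_t>(Ho) * Wo);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + static_cast<size_t>(n) * H * W * C;
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, cols);
    // (HoWo x c2), each column contiguous == one output channel plane
    arma::mat out = cols.t() * wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      out.each_row() += arma::rowvec(b.begin(), c2, false);
    }
    std::copy(out.memptr(), out.memptr() + out.n_elem,
              y.begin() + static_cast<size_t>(n) * Ho * Wo * c2);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix w, NumericVector dy, int k,
                   int stride, int pad, bool need_dx, bool has_bias) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Ho, Wo, c2, N2;
  get_dims4(dy, Ho, Wo, c2, N2);
  arma::mat wm(w.begin(), w.nrow(), c2, false);
  NumericMatrix dw(w.nrow(), c2);
  arma::mat dwm(dw.begin(), w.nrow(), c2, false);
  NumericVector dx = make4(H, W, C, N);
  NumericVector db(c2);
  arma::mat cols(static_cast<size_t>(k) * k * C,
                 static_cast<size_t>(Ho) * Wo);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + static_cast<size_t>(n) * H * W * C;
    arma::mat dyn(const_cast<double *>(dy.begin()) +
                      static_cast<size_t>(n) * Ho * Wo * c2,
                  static_cast<size_t>(Ho) * Wo, c2, false);
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, cols);
    dwm += cols * dyn;
    if (has_bias) {
      arma::rowvec s = arma::sum(dyn, 0);
      for (int c = 0; c < c2; ++c) db[c] += s[c];
    }
    if (need_dx) {
      arma::mat dcols = wm * dyn.t();
      double *dxn = dx.begin() + static_cast<size_t>(n) * H * W * C;
      col2im(dcols, H, W, C, k, stride, pad, Ho, Wo, dxn);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Depthwise convolution: one k x k kernel per channel, w is (k*k, C).

// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, NumericMatrix w, int k,
                            int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y = make4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc =
          x.begin() + (static_cast<size_t>(n) * C + c) * H * W;
      double *yc = y.begin() + (static_cast<size_t>(n) * C + c) * Ho * Wo;
      const double *wc = &w(0, c);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double acc = 0.0;
          for (int ki = 0; ki < k; ++ki) {
            int wi = oi * stride - pad + ki;
            if (wi < 0 || wi >= H) continue;
            for (int kj = 0; kj < k; ++kj) {
              int wj = oj * stride - pad + kj;
              if (wj < 0 || wj >= W) continue;
              acc += xc[static_cast<size_t>(wj) * H + wi] * wc[ki * k + kj];
            }
          }
          yc[static_cast<size_t>(oj) * Ho + oi] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, NumericMatrix w, NumericVector dy, int k,
                   int stride, int pad, bool need_dx) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Ho, Wo, C2, N2;
  get_dims4(dy, Ho, Wo, C2, N2);
  NumericMatrix dw(k * k, C);
  NumericVector dx = make4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc =
          x.begin() + (static_cast<size_t>(n) * C + c) * H * W;
      const double *dyc =
          dy.begin() + (static_cast<size_t>(n) * C + c) * Ho * Wo;
      double *dxc = dx.begin() + (static_cast<size_t>(n) * C + c) * H * W;
      const double *wc = &w(0, c);
      double *dwc = &dw(0, c);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double g = dyc[static_cast<size_t>(oj) * Ho + oi];
          if (g == 0.0) continue;
          for (int ki = 0; ki < k; ++ki) {
            int wi = oi * stride - pad + ki;
            if (wi < 0 || wi >= H) continue;
            for (int kj = 0; kj < k; ++kj) {
              int wj = oj * stride - pad + kj;
              if (wj < 0 || wj >= W) continue;
              dwc[ki * k + kj] += xc[static_cast<size_t>(wj) * H + wi] * g;
              if (need_dx)
                dxc[static_cast<size_t>(wj) * H + wi] += wc[ki * k + kj] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---------------------------------------------------------------------------
// Batch normalisation over (H, W, N) per channel.

// [[Rcpp::export]]
List cpp_bn_fw_train(NumericVector x, NumericVector gamma, NumericVector beta,
                     double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  NumericVector y = make4(H, W, C, N), xhat = make4(H, W, C, N);
  NumericVector mean(C), var(C), invstd(C);
  double m = static_cast<double>(plane) * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v;
    double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *yc = y.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *hc = xhat.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        double h = (xc[i] - mu) * is;
        hc[i] = h;
        yc[i] = gamma[c] * h + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_fw_eval(NumericVector x, NumericVector gamma,
                             NumericVector beta, NumericVector rm,
                             NumericVector rv, double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  NumericVector y = make4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    double is = 1.0 / std::sqrt(rv[c] + eps);
    double a = gamma[c] * is;
    double b = beta[c] - gamma[c] * rm[c] * is;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *yc = y.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) yc[i] = a * xc[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector dy, NumericVector xhat, NumericVector invstd,
               NumericVector gamma) {
  int H, W, C, N;
  get_dims4(dy, H, W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  double m = static_cast<double>(plane) * N;
  NumericVector dx = make4(H, W, C, N), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyh = 0.0;
    for (int n = 0; n < N; ++n) {
      const double *dyc =
          dy.begin() + (static_cast<size_t>(n) * C + c) * plane;
      const double *hc =
          xhat.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        sdy += dyc[i];
        sdyh += dyc[i] * hc[i];
      }
    }
    dgamma[c] = sdyh;
    dbeta[c] = sdy;
    double k1 = sdy / m, k2 = sdyh / m;
    double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double *dyc =
          dy.begin() + (static_cast<size_t>(n) * C + c) * plane;
      const double *hc =
          xhat.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *dxc = dx.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (size_t i = 0; i < plane; ++i)
        dxc[i] = a * (dyc[i] - k1 - hc[i] * k2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---------------------------------------------------------------------------
// Elementwise activations. type: 0 = linear, 1 = swish/SiLU, 2 = hardswish.

// [[Rcpp::export]]
NumericVector cpp_act_fw(NumericVector x, int type) {
  NumericVector y = clone(x);
  R_xlen_t n = x.size();
  if (type == 1) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = x[i];
      y[i] = v / (1.0 + std::exp(-v));
    }
  } else if (type == 2) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = x[i];
      double r = v + 3.0;
      if (r < 0) r = 0; else if (r > 6) r = 6;
      y[i] = v * r / 6.0;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_act_bw(NumericVector x, NumericVector dy, int type) {
  NumericVector dx = clone(dy);
  R_xlen_t n = x.size();
  if (type == 1) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double s = 1.0 / (1.0 + std::exp(-x[i]));
      dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
    }
  } else if (type == 2) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = x[i], g;
      if (v >= 3.0) g = 1.0;
      else if (v <= -3.0) g = 0.0;
      else g = v / 3.0 + 0.5;
      dx[i] = dy[i] * g;
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Max pooling, stride 1, "same" padding (used by the SPP block).

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int p = k / 2;
  NumericVector y = make4(H, W, C, N);
  IntegerVector idx(x.size());
  size_t plane = static_cast<size_t>(H) * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *yc = y.begin() + (static_cast<size_t>(n) * C + c) * plane;
      int *ic = idx.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (int oj = 0; oj < W; ++oj) {
        for (int oi = 0; oi < H; ++oi) {
          double best = -HUGE_VAL;
          int bi = 0;
          for (int kj = 0; kj < k; ++kj) {
            int wj = oj - p + kj;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int wi = oi - p + ki;
              if (wi < 0 || wi >= H) continue;
              double v = xc[static_cast<size_t>(wj) * H + wi];
              if (v > best) { best = v; bi = wj * H + wi; }
            }
          }
          yc[static_cast<size_t>(oj) * H + oi] = best;
          ic[static_cast<size_t>(oj) * H + oi] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx) {
  int H, W, C, N;
  get_dims4(dy, H, W, C, N);
  NumericVector dx = make4(H, W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *dyc =
          dy.begin() + (static_cast<size_t>(n) * C + c) * plane;
      const int *ic = idx.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *dxc = dx.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) dxc[ic[i]] += dyc[i];
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Nearest-neighbour x2 upsampling (PANet neck).

// [[Rcpp::export]]
NumericVector cpp_up_nearest2_fw(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector y = make4(2 * H, 2 * W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  size_t plane2 = plane * 4;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *yc = y.begin() + (static_cast<size_t>(n) * C + c) * plane2;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double v = xc[static_cast<size_t>(j) * H + i];
          size_t b = static_cast<size_t>(2 * j) * 2 * H + 2 * i;
          yc[b] = v; yc[b + 1] = v;
          yc[b + 2 * H] = v; yc[b + 2 * H + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up_nearest2_bw(NumericVector dy) {
  int H2, W2, C, N;
  get_dims4(dy, H2, W2, C, N);
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx = make4(H, W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  size_t plane2 = static_cast<size_t>(H2) * W2;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dyc =
          dy.begin() + (static_cast<size_t>(n) * C + c) * plane2;
      double *dxc = dx.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          size_t b = static_cast<size_t>(2 * j) * H2 + 2 * i;
          dxc[static_cast<size_t>(j) * H + i] =
              dyc[b] + dyc[b + 1] + dyc[b + H2] + dyc[b + H2 + 1];
        }
    }
  return dx;
}

// ---------------------------------------------------------------------------
// Bilinear resampling. align_corners = false uses the pixel-centre
// convention src = (dst + 0.5) * in/out - 0.5; align_corners = true maps
// grid nodes to grid nodes.

static inline void bil_coef(int out, int in, bool align, int o, int &i0,
                            int &i1, double &w1) {
  double src;
  if (align) {
    src = (out == 1) ? 0.0
                     : static_cast<double>(o) * (in - 1) / (out - 1);
  } else {
    src = (o + 0.5) * static_cast<double>(in) / out - 0.5;
  }
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = static_cast<int>(std::floor(src));
  i1 = (i0 + 1 < in) ? i0 + 1 : i0;
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fw(NumericVector x, int out_h, int out_w,
                              bool align_corners) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector y = make4(out_h, out_w, C, N);
  std::vector<int> r0(out_h), r1(out_h), c0(out_w), c1(out_w);
  std::vector<double> rw(out_h), cw(out_w);
  for (int i = 0; i < out_h; ++i) bil_coef(out_h, H, align_corners, i, r0[i], r1[i], rw[i]);
  for (int j = 0; j < out_w; ++j) bil_coef(out_w, W, align_corners, j, c0[j], c1[j], cw[j]);
  size_t plane = static_cast<size_t>(H) * W;
  size_t plane_o = static_cast<size_t>(out_h) * out_w;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (static_cast<size_t>(n) * C + c) * plane;
      double *yc = y.begin() + (static_cast<size_t>(n) * C + c) * plane_o;
      for (int j = 0; j < out_w; ++j) {
        double wc1 = cw[j], wc0 = 1.0 - wc1;
        const double *colA = xc + static_cast<size_t>(c0[j]) * H;
        const double *colB = xc + static_cast<size_t>(c1[j]) * H;
        for (int i = 0; i < out_h; ++i) {
          double wr1 = rw[i], wr0 = 1.0 - wr1;
          yc[static_cast<size_t>(j) * out_h + i] =
              wc0 * (wr0 * colA[r0[i]] + wr1 * colA[r1[i]]) +
              wc1 * (wr0 * colB[r0[i]] + wr1 * colB[r1[i]]);
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bw(NumericVector dy, int in_h, int in_w,
                              bool align_corners) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  NumericVector dx = make4(in_h, in_w, C, N);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> rw(Ho), cw(Wo);
  for (int i = 0; i < Ho; ++i) bil_coef(Ho, in_h, align_corners, i, r0[i], r1[i], rw[i]);
  for (int j = 0; j < Wo; ++j) bil_coef(Wo, in_w, align_corners, j, c0[j], c1[j], cw[j]);
  size_t plane = static_cast<size_t>(in_h) * in_w;
  size_t plane_o = static_cast<size_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dyc =
          dy.begin() + (static_cast<size_t>(n) * C + c) * plane_o;
      double *dxc = dx.begin() + (static_cast<size_t>(n) * C + c) * plane;
      for (int j = 0; j < Wo; ++j) {
        double wc1 = cw[j], wc0 = 1.0 - wc1;
        for (int i = 0; i < Ho; ++i) {
          double g = dyc[static_cast<size_t>(j) * Ho + i];
          double wr1 = rw[i], wr0 = 1.0 - wr1;
          dxc[static_cast<size_t>(c0[j]) * in_h + r0[i]] += wc0 * wr0 * g;
          dxc[static_cast<size_t>(c0[j]) * in_h + r1[i]] += wc0 * wr1 * g;
          dxc[static_cast<size_t>(c1[j]) * in_h + r0[i]] += wc1 * wr0 * g;
          dxc[static_cast<size_t>(c1[j]) * in_h + r1[i]] += wc1 * wr1 * g;
        }
      }
    }
  return dx;
}

// ---------------------------------------------------------------------------
// Focus stem slicing: (H, W, C) -> (H/2, W/2, 4C), channel blocks in the
// order (even rows, even cols), (odd, even), (even, odd), (odd, odd).

// [[Rcpp::export]]
NumericVector cpp_focus_fw(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Hh = H / 2, Wh = W / 2;
  NumericVector y = make4(Hh, Wh, 4 * C, N);
  size_t plane = static_cast<size_t>(H) * W;
  size_t planeh = static_cast<size_t>(Hh) * Wh;
  const int ro[4] = {0, 1, 0, 1}, co[4] = {0, 0, 1, 1};
  for (int n = 0; n < N; ++n)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < C; ++c) {
        const double *xc =
            x.begin() + (static_cast<size_t>(n) * C + c) * plane;
        double *yc = y.begin() +
                     (static_cast<size_t>(n) * 4 * C + b * C + c) * planeh;
        for (int j = 0; j < Wh; ++j)
          for (int i = 0; i < Hh; ++i)
            yc[static_cast<size_t>(j) * Hh + i] =
                xc[static_cast<size_t>(2 * j + co[b]) * H + 2 * i + ro[b]];
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_focus_bw(NumericVector dy, int H, int W) {
  int Hh, Wh, C4, N;
  get_dims4(dy, Hh, Wh, C4, N);
  int C = C4 / 4;
  NumericVector dx = make4(H, W, C, N);
  size_t plane = static_cast<size_t>(H) * W;
  size_t planeh = static_cast<size_t>(Hh) * Wh;
  const int ro[4] = {0, 1, 0, 1}, co[4] = {0, 0, 1, 1};
  for (int n = 0; n < N; ++n)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < C; ++c) {
        const double *dyc =
            dy.begin() + (static_cast<size_t>(n) * C4 + b * C + c) * planeh;
        double *dxc = dx.begin() + (static_cast<size_t>(n) * C + c) * plane;
        for (int j = 0; j < Wh; ++j)
          for (int i = 0; i < Hh; ++i)
            dxc[static_cast<size_t>(2 * j + co[b]) * H + 2 * i + ro[b]] =
                dyc[static_cast<size_t>(j) * Hh + i];
      }
  return dx;
}
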