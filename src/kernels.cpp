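// Low-level numeric kernels for the segmentation network and surface metrics.
// Tensor layout throughout: R arrays with dim c(C, H, W, N), column-major,
// so element (c,h,w,n) sits at c + C*h + C*H*w + C*H*W*n (0-based).
// Convolution weights: dim c(Cout, Cin_per_group, kh, kw).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Gather one sample/group into a (Cg*kh*kw) x (Ho*Wo) column matrix.
// Row index q = ci + Cg*ki + Cg*kh*kj; for each output position the Cg
// input channels are contiguous in both source and destination, so the
// inner copy is sequential.
static void im2col(const double* x, int C, int H, int W,
                   int c0, int Cg, int kh, int kw,
                   int stride, int pad, int dil,
                   int Ho, int Wo, double* col) {
  const long K = (long)Cg * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col + K * ((long)ho + (long)Ho * wo);
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * stride - pad + kj * dil;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * stride - pad + ki * dil;
          double* d = dst + (long)Cg * (ki + kh * kj);
          if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
            const double* s = x + c0 + (long)C * hi + (long)C * H * wi;
            if (Cg == C) memcpy(d, s, sizeof(double) * Cg);
            else for (int ci = 0; ci < Cg; ++ci) d[ci] = s[ci];
          } else {
            memset(d, 0, sizeof(double) * Cg);
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the input gradient.
static void col2im(const double* col, int C, int H, int W,
                   int c0, int Cg, int kh, int kw,
                   int stride, int pad, int dil,
                   int Ho, int Wo, double* dx) {
  const long K = (long)Cg * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = col + K * ((long)ho + (long)Ho * wo);
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * stride - pad + kj * dil;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * stride - pad + ki * dil;
          if (hi < 0 || hi >= H) continue;
          const double* s = src + (long)Cg * (ki + kh * kj);
          double* d = dx + c0 + (long)C * hi + (long)C * H * wi;
          for (int ci = 0; ci < Cg; ++ci) d[ci] += s[ci];
        }
      }
    }
  }
}

// Weights are held in GEMM layout: a K x Cout matrix (K = Cg*kh*kw), the
// columns of group g being the contiguous block [g*Coutg, (g+1)*Coutg).
// Column q ordering within K: q = ci + Cg*ki + Cg*kh*kj.

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix wt, Nullable<NumericVector> bias,
                         IntegerVector kdim, int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int kh = kdim[0], kw = kdim[1];
  const int Cout = wt.ncol();
  const long K = wt.nrow();
  const int Cg = C / groups;
  if ((long)Cg * kh * kw != K) stop("conv2d: weight shape mismatch");
  if (Cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  const int Coutg = Cout / groups;
  const int Ho = out_size(H, kh, stride, pad, dil);
  const int Wo = out_size(W, kw, stride, pad, dil);

  const arma::mat Wt(wt.begin(), K, Cout, false, true);
  NumericVector y((long)Cout * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  const long HoWo = (long)Ho * Wo;
  const long cols = HoWo * N;
  const bool unit = (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1);
  arma::mat col;
  if (!unit) col.set_size(K, cols);
  const double* xp = x.begin();
  double* yp = y.begin();
  if (groups == 1) {
    // GEMM straight into the output buffer (same memory layout)
    arma::mat Y(yp, Cout, cols, false, true);
    if (unit) {
      const arma::mat X(const_cast<double*>(xp), C, cols, false, true);
      Y = Wt.t() * X;
    } else {
      for (int n = 0; n < N; ++n)
        im2col(xp + (long)C * H * W * n, C, H, W, 0, C, kh, kw,
               stride, pad, dil, Ho, Wo, col.memptr() + K * HoWo * n);
      Y = Wt.t() * col;
    }
  } else {
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n)
        im2col(xp + (long)C * H * W * n, C, H, W, g * Cg, Cg, kh, kw,
               stride, pad, dil, Ho, Wo, col.memptr() + K * HoWo * n);
      arma::mat out = Wt.cols(g * Coutg, (g + 1) * Coutg - 1).t() * col;
      for (int n = 0; n < N; ++n) {
        double* yn = yp + (long)Cout * HoWo * n;
        const double* on = out.memptr() + (long)Coutg * HoWo * n;
        for (long p = 0; p < HoWo; ++p)
          for (int co = 0; co < Coutg; ++co)
            yn[(g * Coutg + co) + (long)Cout * p] = on[co + (long)Coutg * p];
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (long p = 0; p < (long)Ho * Wo; ++p)
        for (int co = 0; co < Cout; ++co)
          yp[co + (long)Cout * p + (long)Cout * Ho * Wo * n] += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix wt, NumericVector dy,
                IntegerVector kdim, int stride, int pad, int dil, int groups,
                bool need_dx) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int kh = kdim[0], kw = kdim[1];
  const int Cout = wt.ncol();
  const long K = wt.nrow();
  const int Cg = C / groups;
  const int Ho = yd[1], Wo = yd[2];
  const int Coutg = Cout / groups;

  const arma::mat Wt(wt.begin(), K, Cout, false, true);
  NumericMatrix dwt(K, Cout);
  arma::mat dWt(dwt.begin(), K, Cout, false, true);
  NumericVector db(Cout);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;

  const long HoWo = (long)Ho * Wo;
  const long cols = HoWo * N;
  const bool unit = (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  if (groups == 1) {
    const arma::mat dY(const_cast<double*>(dyp), Cout, cols, false, true);
    if (unit) {
      const arma::mat X(const_cast<double*>(xp), C, cols, false, true);
      dWt = X * dY.t();
      if (need_dx) {
        arma::mat dX(dx.begin(), C, cols, false, true);
        dX = Wt * dY;
      }
    } else {
      arma::mat col(K, cols);
      for (int n = 0; n < N; ++n)
        im2col(xp + (long)C * H * W * n, C, H, W, 0, C, kh, kw,
               stride, pad, dil, Ho, Wo, col.memptr() + K * HoWo * n);
      dWt = col * dY.t();
      if (need_dx) {
        arma::mat dcol = Wt * dY; // K x cols
        for (int n = 0; n < N; ++n)
          col2im(dcol.memptr() + K * HoWo * n, C, H, W, 0, C, kh, kw,
                 stride, pad, dil, Ho, Wo, dx.begin() + (long)C * H * W * n);
      }
    }
  } else {
    arma::mat col(K, cols);
    arma::mat dYgT(cols, Coutg);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        const double* dyn = dyp + (long)Cout * HoWo * n;
        for (long p = 0; p < HoWo; ++p)
          for (int co = 0; co < Coutg; ++co)
            dYgT(p + HoWo * n, co) = dyn[(g * Coutg + co) + (long)Cout * p];
        im2col(xp + (long)C * H * W * n, C, H, W, g * Cg, Cg, kh, kw,
               stride, pad, dil, Ho, Wo, col.memptr() + K * HoWo * n);
      }
      dWt.cols(g * Coutg, (g + 1) * Coutg - 1) = col * dYgT; // K x Coutg
      if (need_dx) {
        arma::mat dcol = Wt.cols(g * Coutg, (g + 1) * Coutg - 1) * dYgT.t();
        for (int n = 0; n < N; ++n)
          col2im(dcol.memptr() + K * HoWo * n, C, H, W, g * Cg, Cg, kh, kw,
                 stride, pad, dil, Ho, Wo, dx.begin() + (long)C * H * W * n);
      }
    }
  }
  for (int n = 0; n < N; ++n) {
    const double* dyn = dyp + (long)Cout * HoWo * n;
    for (long p = 0; p < HoWo; ++p)
      for (int co = 0; co < Cout; ++co)
        db[co] += dyn[co + (long)Cout * p];
  }
  return List::create(_["dx"] = dx, _["dw"] = dwt, _["db"] = db);
}

// In-place Adam update of one parameter block; param, m and v are mutated.
// [[Rcpp::export(name = ".adam_update")]]
void adam_update(NumericVector param, NumericVector grad,
                 NumericVector m, NumericVector v,
                 double lr, double beta1, double beta2, double eps, int t) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  const R_xlen_t n = param.size();
  double* p = param.begin();
  const double* g = grad.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * g[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * g[i] * g[i];
    p[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1), Wo = out_size(W, k, stride, pad, 1);
  NumericVector y((long)C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  IntegerVector idx(y.size()); // linear (h + H*w) source index per output element
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (long)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -1e300; int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xn[c + (long)C * hi + (long)C * H * wi];
              if (v > best) { best = v; bidx = hi + H * wi; }
            }
          }
          long o = c + (long)C * ho + (long)C * Ho * wo + (long)C * Ho * Wo * n;
          yp[o] = (bidx < 0) ? 0.0 : best;
          ip[o] = bidx;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[1], Wo = yd[2];
  NumericVector dx((long)C * H * W * N);
  dx.attr("dim") = xdim;
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (long p = 0; p < (long)Ho * Wo; ++p)
      for (int c = 0; c < C; ++c) {
        long o = c + (long)C * p + (long)C * Ho * Wo * n;
        if (ip[o] >= 0)
          dxp[c + (long)C * ip[o] + (long)C * H * W * n] += dyp[o];
      }
  return dx;
}

// Bilinear x2 upsampling (half-pixel centres, align_corners = false).
// [[Rcpp::export(name = ".upsample2x_fwd")]]
NumericVector upsample2x_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((long)C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  std::vector<int> h0(Ho), h1(Ho); std::vector<double> hw(Ho);
  std::vector<int> w0(Wo), w1(Wo); std::vector<double> ww(Wo);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    int i0 = (int)std::floor(s);
    double f = s - i0;
    h0[o] = std::min(std::max(i0, 0), H - 1);
    h1[o] = std::min(std::max(i0 + 1, 0), H - 1);
    hw[o] = f;
  }
  for (int o = 0; o < Wo; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    int i0 = (int)std::floor(s);
    double f = s - i0;
    w0[o] = std::min(std::max(i0, 0), W - 1);
    w1[o] = std::min(std::max(i0 + 1, 0), W - 1);
    ww[o] = f;
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (long)C * H * W * n;
    double* yn = yp + (long)C * Ho * Wo * n;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double a = (1 - hw[ho]) * (1 - ww[wo]), b = hw[ho] * (1 - ww[wo]);
        double cc = (1 - hw[ho]) * ww[wo], d = hw[ho] * ww[wo];
        const double *p00 = xn + (long)C * h0[ho] + (long)C * H * w0[wo];
        const double *p10 = xn + (long)C * h1[ho] + (long)C * H * w0[wo];
        const double *p01 = xn + (long)C * h0[ho] + (long)C * H * w1[wo];
        const double *p11 = xn + (long)C * h1[ho] + (long)C * H * w1[wo];
        double* out = yn + (long)C * ho + (long)C * Ho * wo;
        for (int c = 0; c < C; ++c)
          out[c] = a * p00[c] + b * p10[c] + cc * p01[c] + d * p11[c];
      }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2x_bwd")]]
NumericVector upsample2x_bwd(NumericVector dy, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[1], Wo = yd[2];
  NumericVector dx((long)C * H * W * N);
  dx.attr("dim") = xdim;
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    const double* dyn = dyp + (long)C * Ho * Wo * n;
    double* dxn = dxp + (long)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      double s = (wo + 0.5) / 2.0 - 0.5;
      int j0 = (int)std::floor(s);
      double fw = s - j0;
      int W0 = std::min(std::max(j0, 0), W - 1), W1 = std::min(std::max(j0 + 1, 0), W - 1);
      for (int ho = 0; ho < Ho; ++ho) {
        double t = (ho + 0.5) / 2.0 - 0.5;
        int i0 = (int)std::floor(t);
        double fh = t - i0;
        int H0 = std::min(std::max(i0, 0), H - 1), H1 = std::min(std::max(i0 + 1, 0), H - 1);
        const double* g = dyn + (long)C * ho + (long)C * Ho * wo;
        double a = (1 - fh) * (1 - fw), b = fh * (1 - fw), cc = (1 - fh) * fw, d = fh * fw;
        double *p00 = dxn + (long)C * H0 + (long)C * H * W0;
        double *p10 = dxn + (long)C * H1 + (long)C * H * W0;
        double *p01 = dxn + (long)C * H0 + (long)C * H * W1;
        double *p11 = dxn + (long)C * H1 + (long)C * H * W1;
        for (int c = 0; c < C; ++c) {
          p00[c] += a * g[c]; p10[c] += b * g[c];
          p01[c] += cc * g[c]; p11[c] += d * g[c];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".gn_fwd")]]
List gn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            int groups, double eps) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cg = C / groups;
  const long M = (long)Cg * H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericMatrix mean(groups, N), invstd(groups, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      double s = 0, s2 = 0;
      for (long p = 0; p < (long)H * W; ++p)
        for (int ci = 0; ci < Cg; ++ci) {
          double v = xp[(g * Cg + ci) + (long)C * p + (long)C * H * W * n];
          s += v; s2 += v * v;
        }
      double mu = s / M;
      double var = s2 / M - mu * mu;
      double is = 1.0 / std::sqrt(var + eps);
      mean(g, n) = mu; invstd(g, n) = is;
      for (long p = 0; p < (long)H * W; ++p)
        for (int ci = 0; ci < Cg; ++ci) {
          int c = g * Cg + ci;
          long o = c + (long)C * p + (long)C * H * W * n;
          yp[o] = gamma[c] * ((xp[o] - mu) * is) + beta[c];
        }
    }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".gn_bwd")]]
List gn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
            NumericMatrix mean, NumericMatrix invstd, int groups) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cg = C / groups;
  const long M = (long)Cg * H * W;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      double mu = mean(g, n), is = invstd(g, n);
      double sum_dxh = 0, sum_dxh_xh = 0;
      for (long p = 0; p < (long)H * W; ++p)
        for (int ci = 0; ci < Cg; ++ci) {
          int c = g * Cg + ci;
          long o = c + (long)C * p + (long)C * H * W * n;
          double xh = (xp[o] - mu) * is;
          double dxh = dyp[o] * gamma[c];
          sum_dxh += dxh;
          sum_dxh_xh += dxh * xh;
          dgamma[c] += dyp[o] * xh;
          dbeta[c] += dyp[o];
        }
      for (long p = 0; p < (long)H * W; ++p)
        for (int ci = 0; ci < Cg; ++ci) {
          int c = g * Cg + ci;
          long o = c + (long)C * p + (long)C * H * W * n;
          double xh = (xp[o] - mu) * is;
          double dxh = dyp[o] * gamma[c];
          dxp[o] = (is / M) * (M * dxh - sum_dxh - xh * sum_dxh_xh);
        }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// For each row of A (points in mm), the minimum Euclidean distance to rows of B.
// [[Rcpp::export(name = ".min_dist_rows")]]
NumericVector min_dist_rows(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Sample img (H x W matrix) at real-valued source coordinates (1-based),
// bilinear or nearest; coordinates clamped to the image border.
// [[Rcpp::export(name = ".warp2d")]]
NumericMatrix warp2d(NumericMatrix img, NumericMatrix srcr, NumericMatrix srcc,
                     bool nearest) {
  const int H = img.nrow(), W = img.ncol();
  const int Ho = srcr.nrow(), Wo = srcr.ncol();
  NumericMatrix out(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      double r = srcr(i, j) - 1.0, c = srcc(i, j) - 1.0;
      if (nearest) {
        int ri = std::min(std::max((int)std::lround(r), 0), H - 1);
        int ci = std::min(std::max((int)std::lround(c), 0), W - 1);
        out(i, j) = img(ri, ci);
      } else {
        r = std::min(std::max(r, 0.0), (double)(H - 1));
        c = std::min(std::max(c, 0.0), (double)(W - 1));
        int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
        int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double fr = r - r0, fc = c - c0;
        out(i, j) = (1 - fr) * (1 - fc) * img(r0, c0) + fr * (1 - fc) * img(r1, c0) +
                    (1 - fr) * fc * img(r0, c1) + fr * fc * img(r1, c1);
      }
    }
  return out;
}
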