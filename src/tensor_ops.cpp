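// Low-level tensor kernels for the U-Net++ engine.
//
// All tensors are R arrays in column-major (H, W, C, N) layout; kernels are
// (k, k, Cin, Cout).  Convolutions use "same" zero padding and are computed
// per sample as an im2col patch matrix times the flattened kernel (one GEMM
// per sample).  The patch matrix and GEMM run in single precision: the conv
// is the only kernel that touches each input element nine times, so halving
// its memory traffic roughly doubles throughput on one CPU, while weights,
// activations and all other kernels stay in double precision.  1x1
// convolutions skip im2col entirely (the input slab already is the patch
// matrix).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill P (H*W x k*k*C) with padded patches of one (H,W,C) sample, converting
// to float.  Row i + H*j holds the patch centred at pixel (i,j); column
// q = di + k*dj + k*k*c matches the column-major kernel flattening.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::fmat& P) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int q = di + k * dj + k * k * c;
        float* Pq = P.colptr(q);
        int off = di - pad;                    // row offset within a column
        int lo = off < 0 ? -off : 0;           // valid output rows [lo, hi)
        int hi = off > 0 ? H - off : H;
        for (int j = 0; j < W; ++j) {
          int jj = j + dj - pad;
          float* Pcol = Pq + (size_t)H * j;
          if (jj < 0 || jj >= W) {
            std::fill(Pcol, Pcol + H, 0.0f);
            continue;
          }
          const double* xcol = xc + (size_t)H * jj + off;
          if (lo > 0) std::fill(Pcol, Pcol + lo, 0.0f);
          for (int i = lo; i < hi; ++i) Pcol[i] = (float)xcol[i];
          if (hi < H) std::fill(Pcol + hi, Pcol + H, 0.0f);
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add float patch gradients onto sample dx.
static void col2im(double* dx, int H, int W, int C, int k, int pad,
                   const arma::fmat& dP) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int q = di + k * dj + k * k * c;
        const float* Pq = dP.colptr(q);
        int off = di - pad;
        int lo = off < 0 ? -off : 0;
        int hi = off > 0 ? H - off : H;
        for (int j = 0; j < W; ++j) {
          int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          const float* Pcol = Pq + (size_t)H * j;
          double* dxcol = dxc + (size_t)H * jj + off;
          for (int i = lo; i < hi; ++i) dxcol[i] += (double)Pcol[i];
        }
      }
    }
  }
}

static arma::fmat to_fmat(const double* p, size_t nr, size_t nc) {
  arma::fmat out(nr, nc);
  float* o = out.memptr();
  for (size_t t = 0; t < nr * nc; ++t) o[t] = (float)p[t];
  return out;
}

// Patch matrices built by a training forward pass, keyed by layer slot and
// consumed (and released) by the matching backward pass.  Purely an
// avoid-recompute cache: results are identical with or without it.
static std::map<int, std::vector<arma::fmat> > g_patch_cache;

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int pad,
                                 int cache_slot = -1) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: kernel expects %d input channels, got %d", wd[2], C);
  size_t HW = (size_t)H * W;

  arma::fmat Wm = to_fmat(w.begin(), (size_t)k * k * C, Cout);
  arma::frowvec bv(Cout);
  for (int co = 0; co < Cout; ++co) bv[co] = (float)b[co];

  NumericVector y((R_xlen_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  std::vector<arma::fmat>* keep = NULL;
  if (cache_slot >= 0 && k > 1) {
    g_patch_cache[cache_slot].assign(N, arma::fmat());
    keep = &g_patch_cache[cache_slot];
  }
  arma::fmat P;
  if (k > 1 && !keep) P.set_size(HW, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * n;
    arma::fmat Y;
    if (k == 1) {
      Y = to_fmat(xn, HW, C) * Wm;
    } else if (keep) {
      (*keep)[n].set_size(HW, (size_t)k * k * C);
      im2col(xn, H, W, C, k, pad, (*keep)[n]);
      Y = (*keep)[n] * Wm;
    } else {
      im2col(xn, H, W, C, k, pad, P);
      Y = P * Wm;
    }
    Y.each_row() += bv;
    double* yn = y.begin() + HW * Cout * n;
    const float* yp = Y.memptr();
    for (size_t t = 0; t < HW * Cout; ++t) yn[t] = (double)yp[t];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad, int cache_slot = -1, bool want_dx = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  size_t HW = (size_t)H * W;

  arma::fmat Wm = to_fmat(w.begin(), (size_t)k * k * C, Cout);

  NumericVector dx((R_xlen_t)HW * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)k * k * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::fmat dWm((size_t)k * k * C, Cout, arma::fill::zeros);
  std::vector<arma::fmat>* kept = NULL;
  std::map<int, std::vector<arma::fmat> >::iterator it =
      g_patch_cache.find(cache_slot);
  if (cache_slot >= 0 && k > 1 && it != g_patch_cache.end() &&
      it->second.size() == (size_t)N &&
      it->second[0].n_rows == HW)
    kept = &it->second;
  arma::fmat P;
  if (k > 1 && !kept) P.set_size(HW, (size_t)k * k * C);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * n;
    arma::fmat dY = to_fmat(dy.begin() + HW * Cout * n, HW, Cout);
    for (int co = 0; co < Cout; ++co) db[co] += (double)arma::accu(dY.col(co));
    double* dxn = dx.begin() + HW * C * n;
    if (k == 1) {
      arma::fmat X = to_fmat(xn, HW, C);
      dWm += X.t() * dY;
      if (want_dx) {
        arma::fmat dX = dY * Wm.t();
        const float* dp = dX.memptr();
        for (size_t t = 0; t < HW * C; ++t) dxn[t] = (double)dp[t];
      }
    } else {
      const arma::fmat& Pn = kept ? (*kept)[n]
                                  : (im2col(xn, H, W, C, k, pad, P), P);
      dWm += Pn.t() * dY;
      if (want_dx) {
        arma::fmat dP = dY * Wm.t();
        col2im(dxn, H, W, C, k, pad, dP);
      }
    }
  }
  if (kept) g_patch_cache.erase(it);
  const float* wp = dWm.memptr();
  for (R_xlen_t t = 0; t < dw.size(); ++t) dw[t] = (double)wp[t];
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Drop any retained patch matrices (used between training runs).
// [[Rcpp::export]]
void cpp_clear_patch_cache() { g_patch_cache.clear(); }

// 2x2 max pooling with stride 2 (H, W must be even); idx holds the 0-based
// linear index of each window argmax so the backward pass can scatter.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int H2 = H / 2, W2 = W / 2;

  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx((R_xlen_t)H2 * W2 * C * N);

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    size_t xo = (size_t)cn * H * W;
    size_t yo = (size_t)cn * H2 * W2;
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        size_t base = xo + (size_t)(2 * j) * H + 2 * i;
        size_t best = base;
        double bv = xp[base];
        size_t cand[3] = {base + 1, base + H, base + H + 1};
        for (int q = 0; q < 3; ++q)
          if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
        yp[yo + (size_t)j * H2 + i] = bv;
        ip[yo + (size_t)j * H2 + i] = (int)best;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(IntegerVector idx, NumericVector dy,
                                    IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[idx[t]] += dy[t];
  return dx;
}

// Bilinear 2x upsampling (half-pixel centres, clamped borders) and its adjoint.
static void up2_weights(int Hout, int Hin, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Hout); i1.resize(Hout); w1.resize(Hout);
  for (int o = 0; o < Hout; ++o) {
    double s = (o + 0.5) * 0.5 - 0.5;
    if (s < 0) s = 0;
    int a = (int)std::floor(s);
    if (a > Hin - 1) a = Hin - 1;
    int b = (a + 1 < Hin) ? a + 1 : a;
    i0[o] = a; i1[o] = b; w1[o] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int H2 = 2 * H, W2 = 2 * W;
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  up2_weights(H2, H, ri0, ri1, rw);
  up2_weights(W2, W, cj0, cj1, cw);

  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = xp + (size_t)cn * H * W;
    double* ys = yp + (size_t)cn * H2 * W2;
    for (int oj = 0; oj < W2; ++oj) {
      const double* xc0 = xs + (size_t)cj0[oj] * H;
      const double* xc1 = xs + (size_t)cj1[oj] * H;
      double wc = cw[oj];
      double* yc = ys + (size_t)oj * H2;
      for (int oi = 0; oi < H2; ++oi) {
        double wr = rw[oi];
        double v0 = (1 - wr) * xc0[ri0[oi]] + wr * xc0[ri1[oi]];
        double v1 = (1 - wr) * xc1[ri0[oi]] + wr * xc1[ri1[oi]];
        yc[oi] = (1 - wc) * v0 + wc * v1;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int H2 = 2 * H, W2 = 2 * W;
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  up2_weights(H2, H, ri0, ri1, rw);
  up2_weights(W2, W, cj0, cj1, cw);

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    double* xs = xp + (size_t)cn * H * W;
    const double* ds = dp + (size_t)cn * H2 * W2;
    for (int oj = 0; oj < W2; ++oj) {
      double wc = cw[oj];
      double* xc0 = xs + (size_t)cj0[oj] * H;
      double* xc1 = xs + (size_t)cj1[oj] * H;
      const double* dc = ds + (size_t)oj * H2;
      for (int oi = 0; oi < H2; ++oi) {
        double wr = rw[oi], g = dc[oi];
        xc0[ri0[oi]] += (1 - wc) * (1 - wr) * g;
        xc0[ri1[oi]] += (1 - wc) * wr * g;
        xc1[ri0[oi]] += wc * (1 - wr) * g;
        xc1[ri1[oi]] += wc * wr * g;
      }
    }
  }
  return dx;
}

// ---- batch normalization (channel = 3rd margin) -------------------------

// Per-channel mean and biased variance over (H, W, N).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      for (size_t t = 0; t < HW; ++t) { s += p[t]; s2 += p[t] * p[t]; }
    }
    double m = (double)HW * N;
    mean[c] = s / m;
    double v = s2 / m - mean[c] * mean[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(Named("mean") = mean, Named("var") = var);
}

// y = gamma * (x - mean) * invstd + beta; also returns xhat for backward.
// [[Rcpp::export]]
List cpp_bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
                  NumericVector mean, NumericVector invstd,
                  bool keep_xhat) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector xhat;
  if (keep_xhat) { xhat = NumericVector(x.size()); xhat.attr("dim") = xd; }
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      size_t o = HW * (c + (size_t)C * n);
      const double* px = x.begin() + o;
      double* py = y.begin() + o;
      if (keep_xhat) {
        double* ph = xhat.begin() + o;
        for (size_t t = 0; t < HW; ++t) {
          ph[t] = (px[t] - mu) * is;
          py[t] = g * ph[t] + b;
        }
      } else {
        for (size_t t = 0; t < HW; ++t) py[t] = g * (px[t] - mu) * is + b;
      }
    }
  }
  if (keep_xhat)
    return List::create(Named("y") = y, Named("xhat") = xhat);
  return List::create(Named("y") = y);
}

// Standard batch-norm backward from dy and the cached xhat.
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector dy, NumericVector xhat,
                     NumericVector gamma, NumericVector invstd) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      size_t o = HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + o;
      const double* ph = xhat.begin() + o;
      for (size_t t = 0; t < HW; ++t) { sb += pd[t]; sg += pd[t] * ph[t]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    double gi = gamma[c] * invstd[c], a = sb / m, b = sg / m;
    for (int n = 0; n < N; ++n) {
      size_t o = HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + o;
      const double* ph = xhat.begin() + o;
      double* px = dx.begin() + o;
      for (size_t t = 0; t < HW; ++t)
        px[t] = gi * (pd[t] - a - ph[t] * b);
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
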