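// CNN primitives for the inpainting network.
//
// All image batches are R arrays in H x W x C x N layout (column-major), so a
// per-sample channel block is contiguous. Convolutions are 3x3, stride 1,
// zero-padded to preserve spatial size; downsampling happens only in 2x2
// max-pool layers and upsampling only in nearest-neighbour x2 layers.
// Convolution uses the offset-GEMM formulation over sample-interleaved
// chunks (see below) with a 3 x 3 x Cin x Cout kernel tensor. Batch
// normalization and the activations are implemented here as well, and conv +
// batchnorm + ReLU is additionally fused into single block kernels, so the
// training loop spends its time in compiled code with few allocations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// persistent grow-only scratch so the training loop does not page-fault on
// fresh multi-megabyte allocations every call; wrapped as arma views
static double* scratch(int which, size_t n) {
  static std::vector<double> bufs[4];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which].data();
}

// ---------------------------------------------------------------------------
// Convolution via the offset-GEMM ("shift") formulation.
//
// A chunk of NC samples is repacked sample-interleaved: X2 is a column-major
// (NC*H*W) x C matrix with row index s + NC*(h + H*w). A spatial shift
// (di, dj) then shifts the row index uniformly by NC*(di + H*dj) for every
// sample at once, so each of the 9 kernel offsets reduces to dense GEMMs on
// contiguous row ranges (whole-matrix when di == 0, per-column otherwise),
// with no im2col buffer at all.

#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

static const int NC = 4;  // samples per repacked chunk

static void packX2(const double* x, int H, int W, int C, int nc, int nch,
                   double* X2) {
  // x: per-sample (HW x C) blocks; X2: (nch*HW) x C, row = s + nch*hw
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* dst = X2 + (size_t)nch * HW * c;
    for (int s = 0; s < nc; ++s) {
      const double* src = x + HW * (c + (size_t)C * s);
      for (size_t i = 0; i < HW; ++i) dst[s + (size_t)nch * i] = src[i];
    }
  }
}

static void unpackY2(const double* Y2, int H, int W, int C, int nc, int nch,
                     double* y) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* src = Y2 + (size_t)nch * HW * c;
    for (int s = 0; s < nc; ++s) {
      double* dst = y + HW * (c + (size_t)C * s);
      for (size_t i = 0; i < HW; ++i) dst[i] = src[s + (size_t)nch * i];
    }
  }
}

// dense C x Cout copy of the kernel slice at offset (ki, kj)
static void kernelSlice(const double* wgt, int C, int Cout, int ki, int kj,
                        double* Wk) {
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      Wk[c + (size_t)C * co] = wgt[ki + 3 * kj + 9 * c + (size_t)9 * C * co];
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector wgt, NumericVector bias,
                           IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = wdim[3];
  if (wdim[2] != C) stop("channel mismatch between input and kernel");
  NumericVector y(no_init((size_t)H * W * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const size_t HW = (size_t)H * W;
  const int nch = std::min(NC, N);
  const int LD = nch * HW;          // rows of X2 / Y2
  double* X2 = scratch(0, (size_t)LD * C);
  double* Y2 = scratch(1, (size_t)LD * Cout);
  std::vector<double> Wk((size_t)C * Cout);
  const double one = 1.0;
  for (int n0 = 0; n0 < N; n0 += nch) {
    const int nc = std::min(nch, N - n0);
    packX2(x.begin() + HW * C * (size_t)n0, H, W, C, nc, nch, X2);
    for (int co = 0; co < Cout; ++co)
      std::fill(Y2 + (size_t)LD * co, Y2 + (size_t)LD * (co + 1), bias[co]);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int di = ki - 1, dj = kj - 1;
        kernelSlice(wgt.begin(), C, Cout, ki, kj, Wk.data());
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        const int w0 = std::max(0, -dj), w1 = std::min(W, W - dj);
        const int off = nch * (di + H * dj);
        if (di == 0) {
          const int M = nch * H * (w1 - w0);
          const int start = nch * H * w0;
          F77_CALL(dgemm)("N", "N", &M, &Cout, &C, &one,
                          X2 + start + off, &LD, Wk.data(), &C, &one,
                          Y2 + start, &LD FCONE FCONE);
        } else {
          const int M = nch * (h1 - h0);
          for (int w = w0; w < w1; ++w) {
            const int start = nch * (h0 + H * w);
            F77_CALL(dgemm)("N", "N", &M, &Cout, &C, &one,
                            X2 + start + off, &LD, Wk.data(), &C, &one,
                            Y2 + start, &LD FCONE FCONE);
          }
        }
      }
    }
    unpackY2(Y2, H, W, Cout, nc, nch, y.begin() + HW * Cout * (size_t)n0);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, NumericVector wgt, NumericVector dy,
                  IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = wdim[3];
  NumericVector dx(no_init((size_t)H * W * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(9 * C * Cout);  // zero-filled: accumulated across chunks
  dw.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  NumericVector db(Cout);
  const size_t HW = (size_t)H * W;
  const int nch = std::min(NC, N);
  const int LD = nch * HW;
  double* X2 = scratch(0, (size_t)LD * C);
  double* dY2 = scratch(1, (size_t)LD * Cout);
  double* dX2 = scratch(2, (size_t)LD * C);
  std::vector<double> Wk((size_t)C * Cout), dWk((size_t)C * Cout);
  const double one = 1.0, zero = 0.0;
  for (int n0 = 0; n0 < N; n0 += nch) {
    const int nc = std::min(nch, N - n0);
    if (nc < nch) {   // zero-pad the tail chunk
      std::fill(X2, X2 + (size_t)LD * C, 0.0);
      std::fill(dY2, dY2 + (size_t)LD * Cout, 0.0);
    }
    packX2(x.begin() + HW * C * (size_t)n0, H, W, C, nc, nch, X2);
    packX2(dy.begin() + HW * Cout * (size_t)n0, H, W, Cout, nc, nch, dY2);
    std::fill(dX2, dX2 + (size_t)LD * C, 0.0);
    double* dbp = db.begin();
    for (int co = 0; co < Cout; ++co) {
      double sb = 0;
      const double* col = dY2 + (size_t)LD * co;
      for (int i = 0; i < LD; ++i) sb += col[i];
      dbp[co] += sb;
    }
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int di = ki - 1, dj = kj - 1;
        kernelSlice(wgt.begin(), C, Cout, ki, kj, Wk.data());
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        const int w0 = std::max(0, -dj), w1 = std::min(W, W - dj);
        const int off = nch * (di + H * dj);
        std::fill(dWk.begin(), dWk.end(), 0.0);
        if (di == 0) {
          const int M = nch * H * (w1 - w0);
          const int start = nch * H * w0;
          F77_CALL(dgemm)("T", "N", &C, &Cout, &M, &one,
                          X2 + start + off, &LD, dY2 + start, &LD, &zero,
                          dWk.data(), &C FCONE FCONE);
          F77_CALL(dgemm)("N", "T", &M, &C, &Cout, &one,
                          dY2 + start, &LD, Wk.data(), &C, &one,
                          dX2 + start + off, &LD FCONE FCONE);
        } else {
          const int M = nch * (h1 - h0);
          for (int w = w0; w < w1; ++w) {
            const int start = nch * (h0 + H * w);
            F77_CALL(dgemm)("T", "N", &C, &Cout, &M, &one,
                            X2 + start + off, &LD, dY2 + start, &LD, &one,
                            dWk.data(), &C FCONE FCONE);
            F77_CALL(dgemm)("N", "T", &M, &C, &Cout, &one,
                            dY2 + start, &LD, Wk.data(), &C, &one,
                            dX2 + start + off, &LD FCONE FCONE);
          }
        }
        double* dwp = dw.begin();
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            dwp[ki + 3 * kj + 9 * c + (size_t)9 * C * co] +=
              dWk[c + (size_t)C * co];
      }
    }
    unpackY2(dX2, H, W, C, nc, nch, dx.begin() + HW * C * (size_t)n0);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(no_init((size_t)Ho * Wo * C * N));  // linear offset within sample
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t xs = (size_t)H * W * C;
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + xs * n;
    for (int c = 0; c < C; ++c) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++o) {
          int best = 2 * h + H * (2 * w) + H * W * c;
          double bv = xn[best];
          const int cand[3] = {2 * h + 1 + H * (2 * w) + H * W * c,
                               2 * h + H * (2 * w + 1) + H * W * c,
                               2 * h + 1 + H * (2 * w + 1) + H * W * c};
          for (int k = 0; k < 3; ++k)
            if (xn[cand[k]] > bv) { bv = xn[cand[k]]; best = cand[k]; }
          yp[o] = bv;
          ip[o] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t xs = (size_t)H * W * C;
  const size_t per = (size_t)(H / 2) * (W / 2) * C;
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    double* dxn = dx.begin() + xs * n;
    for (size_t k = 0; k < per; ++k, ++o) dxn[ip[o]] += dp[o];
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* xq = x.begin() + (size_t)H * W * q;
    double* yq = y.begin() + (size_t)Ho * Wo * q;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        yq[h + (size_t)Ho * w] = xq[h / 2 + (size_t)H * (w / 2)];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector dy, IntegerVector ydim) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* dyq = dy.begin() + (size_t)Ho * Wo * q;
    double* dxq = dx.begin() + (size_t)H * W * q;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        dxq[h / 2 + (size_t)H * (w / 2)] += dyq[h + (size_t)Ho * w];
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Batch normalization (per channel over H, W, N) and activations

// [[Rcpp::export(name = ".cpp_bn_fwd_train")]]
List cpp_bn_fwd_train(NumericVector x, NumericVector gamma, NumericVector beta,
                      IntegerVector xdim, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W, xs = HW * C;
  const double M = (double)HW * N;
  NumericVector mu(C), var(C), invstd(C);
  double* mup = mu.begin();
  double* varp = var.begin();
  double* isp = invstd.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + xs * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + HW * c;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mup[c] += s;
      varp[c] += s2;
    }
  }
  for (int c = 0; c < C; ++c) {
    mup[c] /= M;
    varp[c] = varp[c] / M - mup[c] * mup[c];
    if (varp[c] < 0) varp[c] = 0;
    isp[c] = 1.0 / std::sqrt(varp[c] + eps);
  }
  NumericVector y(no_init(x.size())), xhat(no_init(x.size()));
  y.attr("dim") = xdim;
  xhat.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + xs * n;
    double* yn = y.begin() + xs * n;
    double* hn = xhat.begin() + xs * n;
    for (int c = 0; c < C; ++c) {
      const double m = mup[c], is = isp[c], g = gamma[c], b = beta[c];
      const double* xc = xn + HW * c;
      double* yc = yn + HW * c;
      double* hc = hn + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        const double h = (xc[i] - m) * is;
        hc[i] = h;
        yc[i] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".cpp_bn_fwd_infer")]]
NumericVector cpp_bn_fwd_infer(NumericVector x, NumericVector gamma,
                               NumericVector beta, NumericVector rm,
                               NumericVector rv, IntegerVector xdim,
                               double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W, xs = HW * C;
  NumericVector y(no_init(x.size()));
  y.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + xs * n;
    double* yn = y.begin() + xs * n;
    for (int c = 0; c < C; ++c) {
      const double is = 1.0 / std::sqrt(rv[c] + eps);
      const double m = rm[c], g = gamma[c], b = beta[c];
      const double* xc = xn + HW * c;
      double* yc = yn + HW * c;
      for (size_t i = 0; i < HW; ++i) yc[i] = g * (xc[i] - m) * is + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
                NumericVector gamma, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W, xs = HW * C;
  const double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n) {
    const double* dn = dy.begin() + xs * n;
    const double* hn = xhat.begin() + xs * n;
    for (int c = 0; c < C; ++c) {
      const double* dc = dn + HW * c;
      const double* hc = hn + HW * c;
      double sg = 0, sb = 0;
      for (size_t i = 0; i < HW; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
      dgamma[c] += sg;
      dbeta[c] += sb;
    }
  }
  NumericVector dx(no_init(dy.size()));
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* dn = dy.begin() + xs * n;
    const double* hn = xhat.begin() + xs * n;
    double* xn = dx.begin() + xs * n;
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c], is = invstd[c];
      const double sd = dbeta[c], sdh = dgamma[c];
      const double* dc = dn + HW * c;
      const double* hc = hn + HW * c;
      double* xc = xn + HW * c;
      const double k = g * is / M;
      for (size_t i = 0; i < HW; ++i)
        xc[i] = k * (M * dc[i] - sd - hc[i] * sdh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(no_init(dy.size()));
  dx.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* yp = y.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = yp[i] > 0 ? dp[i] : 0;
  return dx;
}

// [[Rcpp::export(name = ".cpp_sigmoid_fwd")]]
NumericVector cpp_sigmoid_fwd(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return y;
}

// ---------------------------------------------------------------------------
// Fused conv -> batchnorm -> ReLU blocks (the encoder/decoder building
// block). Fusing keeps the batch in two arrays (post-activation y and
// normalized xhat) instead of four and saves two full passes per block.

// [[Rcpp::export(name = ".cpp_block_fwd_train")]]
List cpp_block_fwd_train(NumericVector x, NumericVector wgt, NumericVector bias,
                         NumericVector gamma, NumericVector beta,
                         IntegerVector xdim, IntegerVector wdim, double eps) {
  NumericVector y = cpp_conv_fwd(x, wgt, bias, xdim, wdim);
  const int H = xdim[0], W = xdim[1], N = xdim[3];
  const int C = wdim[3];
  IntegerVector ydim = IntegerVector::create(H, W, C, N);
  const size_t HW = (size_t)H * W, ys = HW * C;
  const double M = (double)HW * N;
  NumericVector mu(C), var(C), invstd(C);
  double* mup = mu.begin();
  double* varp = var.begin();
  double* isp = invstd.begin();
  for (int n = 0; n < N; ++n) {
    const double* yn = y.begin() + ys * n;
    for (int c = 0; c < C; ++c) {
      const double* yc = yn + HW * c;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) { s += yc[i]; s2 += yc[i] * yc[i]; }
      mup[c] += s;
      varp[c] += s2;
    }
  }
  for (int c = 0; c < C; ++c) {
    mup[c] /= M;
    varp[c] = varp[c] / M - mup[c] * mup[c];
    if (varp[c] < 0) varp[c] = 0;
    isp[c] = 1.0 / std::sqrt(varp[c] + eps);
  }
  NumericVector xhat(no_init(y.size()));
  xhat.attr("dim") = ydim;
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + ys * n;
    double* hn = xhat.begin() + ys * n;
    for (int c = 0; c < C; ++c) {
      const double m = mup[c], is = isp[c], g = gamma[c], b = beta[c];
      double* yc = yn + HW * c;
      double* hc = hn + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        const double h = (yc[i] - m) * is;
        hc[i] = h;
        const double a = g * h + b;
        yc[i] = a > 0 ? a : 0;   // in-place BN + ReLU
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".cpp_block_fwd_infer")]]
NumericVector cpp_block_fwd_infer(NumericVector x, NumericVector wgt,
                                  NumericVector bias, NumericVector gamma,
                                  NumericVector beta, NumericVector rm,
                                  NumericVector rv, IntegerVector xdim,
                                  IntegerVector wdim, double eps) {
  NumericVector y = cpp_conv_fwd(x, wgt, bias, xdim, wdim);
  const int H = xdim[0], W = xdim[1], N = xdim[3];
  const int C = wdim[3];
  const size_t HW = (size_t)H * W, ys = HW * C;
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + ys * n;
    for (int c = 0; c < C; ++c) {
      const double is = 1.0 / std::sqrt(rv[c] + eps);
      const double m = rm[c], g = gamma[c], b = beta[c];
      double* yc = yn + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        const double a = g * (yc[i] - m) * is + b;
        yc[i] = a > 0 ? a : 0;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_block_bwd")]]
List cpp_block_bwd(NumericVector dy, NumericVector y, NumericVector xhat,
                   NumericVector invstd, NumericVector gamma,
                   NumericVector x, NumericVector wgt,
                   IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], N = xdim[3];
  const int C = wdim[3];
  IntegerVector ydim = IntegerVector::create(H, W, C, N);
  const size_t HW = (size_t)H * W, ys = HW * C;
  const double M = (double)HW * N;
  // pass 1: masked reductions for dgamma/dbeta
  NumericVector dgamma(C), dbeta(C);
  double* dgp = dgamma.begin();
  double* dbp = dbeta.begin();
  for (int n = 0; n < N; ++n) {
    const double* dn = dy.begin() + ys * n;
    const double* yn = y.begin() + ys * n;
    const double* hn = xhat.begin() + ys * n;
    for (int c = 0; c < C; ++c) {
      const double* dc = dn + HW * c;
      const double* yc = yn + HW * c;
      const double* hc = hn + HW * c;
      double sg = 0, sb = 0;
      for (size_t i = 0; i < HW; ++i) {
        if (yc[i] > 0) { sg += dc[i] * hc[i]; sb += dc[i]; }
      }
      dgp[c] += sg;
      dbp[c] += sb;
    }
  }
  // pass 2: d(conv output), reusing the masked sums
  NumericVector dconv(no_init(dy.size()));
  dconv.attr("dim") = ydim;
  for (int n = 0; n < N; ++n) {
    const double* dn = dy.begin() + ys * n;
    const double* yn = y.begin() + ys * n;
    const double* hn = xhat.begin() + ys * n;
    double* on = dconv.begin() + ys * n;
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c], is = invstd[c];
      const double sb = dbp[c], sg = dgp[c];
      const double k = g * is / M;
      const double* dc = dn + HW * c;
      const double* yc = yn + HW * c;
      const double* hc = hn + HW * c;
      double* oc = on + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        const double dr = yc[i] > 0 ? dc[i] : 0;
        oc[i] = k * (M * dr - sb - hc[i] * sg);
      }
    }
  }
  List cv = cpp_conv_bwd(x, wgt, dconv, xdim, wdim);
  cv["dgamma"] = dgamma;
  cv["dbeta"] = dbeta;
  return cv;
}
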