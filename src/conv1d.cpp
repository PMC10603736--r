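// Float32 GEMM-backed network kernels: 1-D convolution, batch norm and
// leaky ReLU.
//
// Activations cross the R/C++ boundary as double matrices of shape
// (T*B) x C, column-major, row index t + T*b (time fastest).  Convolution
// weights are k x Cin x Cout arrays.  Stride is 1; padding is "same"
// (zero) or circular, so the temporal length T is preserved.
//
// The convolution cores use a per-batch im2col: for each window the
// padded slice is packed into an L2-resident T x (k*Ci) panel and one
// sgemm against the prepacked (k*Ci) x Co weight matrix produces that
// window's T x Co output block in place.  All heavy arithmetic is single
// precision; R-side bookkeeping stays double.

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <dlfcn.h>

using namespace Rcpp;

extern "C" void sgemm_(const char *transa, const char *transb, const int *m,
                       const int *n, const int *k, const float *alpha,
                       const float *a, const int *lda, const float *b,
                       const int *ldb, const float *beta, float *c,
                       const int *ldc);

// Pin OpenBLAS to one thread when the symbol is available: keeps results
// bit-reproducible run-to-run regardless of the host's CPU count.
// [[Rcpp::export]]
void blas_single_thread() {
  typedef void (*setfn)(int);
  setfn f = (setfn)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f) f(1);
}

namespace {

inline void to_float(const double *src, float *dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// per-offset weight slices: Ws[o] is Ci x Co float
void pack_weight_slices(const double *W, float *Ws, int k, int Ci, int Co) {
  for (int o = 0; o < k; ++o)
    for (int co = 0; co < Co; ++co)
      for (int ci = 0; ci < Ci; ++ci)
        Ws[(size_t)o * Ci * Co + ci + (size_t)Ci * co] =
            (float)W[o + (size_t)k * (ci + (size_t)Ci * co)];
}

// Y (TB x Co float) = conv(Xf).  Each window's T x Ci block is copied once
// into a contiguous L2-resident buffer; the k offset GEMMs run on it with
// zero padding realized by restricting the valid row range (or an explicit
// wrapped copy for circular padding).
void conv_core_fwd(const float *Xf, const double *W, float *Y, int T, int B,
                   int Ci, int Co, int k, int circular) {
  const int TB = T * B;
  const int pad = (k - 1) / 2;
  std::vector<float> Ws((size_t)k * Ci * Co), Xl((size_t)T * Ci),
      Yl((size_t)T * Co);
  pack_weight_slices(W, Ws.data(), k, Ci, Co);
  const float one = 1.0f;
  for (int b = 0; b < B; ++b) {
    for (int ci = 0; ci < Ci; ++ci)
      memcpy(Xl.data() + (size_t)T * ci, Xf + (size_t)TB * ci + (size_t)T * b,
             (size_t)T * 4);
    std::fill(Yl.begin(), Yl.end(), 0.0f);
    for (int o = 0; o < k; ++o) {
      const float *Wo = Ws.data() + (size_t)o * Ci * Co;
      const int sh = o - pad;
      if (circular) {
        // wrapped slice of Xl into a scratch panel
        std::vector<float> S((size_t)T * Ci);
        for (int ci = 0; ci < Ci; ++ci) {
          const float *xc = Xl.data() + (size_t)T * ci;
          float *sc = S.data() + (size_t)T * ci;
          for (int t = 0; t < T; ++t) sc[t] = xc[(((t + sh) % T) + T) % T];
        }
        sgemm_("N", "N", &T, &Co, &Ci, &one, S.data(), &T, Wo, &Ci, &one,
               Yl.data(), &T);
      } else {
        const int t0 = std::max(0, -sh);
        const int t1 = std::min(T, T - sh);
        const int M = t1 - t0;
        if (M <= 0) continue;
        sgemm_("N", "N", &M, &Co, &Ci, &one, Xl.data() + t0 + sh, &T, Wo,
               &Ci, &one, Yl.data() + t0, &T);
      }
    }
    for (int co = 0; co < Co; ++co)
      memcpy(Y + (size_t)TB * co + (size_t)T * b, Yl.data() + (size_t)T * co,
             (size_t)T * 4);
  }
}

// dXf (TB x Ci), dW (k x Ci x Co double), db (Co double) from dA float
void conv_core_bwd(const float *Xf, const double *W, const float *dA,
                   float *dXf, double *dW, double *db, int T, int B, int Ci,
                   int Co, int k, int circular) {
  const int TB = T * B;
  const int pad = (k - 1) / 2;
  std::vector<float> Ws((size_t)k * Ci * Co), dWs((size_t)k * Ci * Co, 0.0f),
      Xl((size_t)T * Ci), Gl((size_t)T * Co), dXl((size_t)T * Ci),
      S((size_t)T * Ci);
  pack_weight_slices(W, Ws.data(), k, Ci, Co);
  const float one = 1.0f;
  for (int b = 0; b < B; ++b) {
    for (int ci = 0; ci < Ci; ++ci)
      memcpy(Xl.data() + (size_t)T * ci, Xf + (size_t)TB * ci + (size_t)T * b,
             (size_t)T * 4);
    for (int co = 0; co < Co; ++co)
      memcpy(Gl.data() + (size_t)T * co, dA + (size_t)TB * co + (size_t)T * b,
             (size_t)T * 4);
    std::fill(dXl.begin(), dXl.end(), 0.0f);
    for (int o = 0; o < k; ++o) {
      const float *Wo = Ws.data() + (size_t)o * Ci * Co;
      float *dWo = dWs.data() + (size_t)o * Ci * Co;
      const int sh = o - pad;
      if (circular) {
        for (int ci = 0; ci < Ci; ++ci) {
          const float *xc = Xl.data() + (size_t)T * ci;
          float *sc = S.data() + (size_t)T * ci;
          for (int t = 0; t < T; ++t) sc[t] = xc[(((t + sh) % T) + T) % T];
        }
        sgemm_("T", "N", &Ci, &Co, &T, &one, S.data(), &T, Gl.data(), &T,
               &one, dWo, &Ci);
        // dS = Gl Wo^T, then wrapped scatter-add into dXl
        std::vector<float> dS((size_t)T * Ci, 0.0f);
        const float zero = 0.0f;
        sgemm_("N", "T", &T, &Ci, &Co, &one, Gl.data(), &T, Wo, &Ci, &zero,
               dS.data(), &T);
        for (int ci = 0; ci < Ci; ++ci) {
          float *xc = dXl.data() + (size_t)T * ci;
          const float *sc = dS.data() + (size_t)T * ci;
          for (int t = 0; t < T; ++t) xc[(((t + sh) % T) + T) % T] += sc[t];
        }
      } else {
        const int t0 = std::max(0, -sh);
        const int t1 = std::min(T, T - sh);
        const int M = t1 - t0;
        if (M <= 0) continue;
        sgemm_("T", "N", &Ci, &Co, &M, &one, Xl.data() + t0 + sh, &T,
               Gl.data() + t0, &T, &one, dWo, &Ci);
        sgemm_("N", "T", &M, &Ci, &Co, &one, Gl.data() + t0, &T, Wo, &Ci,
               &one, dXl.data() + t0 + sh, &T);
      }
    }
    for (int ci = 0; ci < Ci; ++ci) {
      float *dst = dXf + (size_t)TB * ci + (size_t)T * b;
      const float *src = dXl.data() + (size_t)T * ci;
      memcpy(dst, src, (size_t)T * 4);
    }
  }
  for (int o = 0; o < k; ++o)
    for (int co = 0; co < Co; ++co)
      for (int ci = 0; ci < Ci; ++ci)
        dW[o + (size_t)k * (ci + (size_t)Ci * co)] =
            (double)dWs[(size_t)o * Ci * Co + ci + (size_t)Ci * co];
  for (int co = 0; co < Co; ++co) {
    const float *gc = dA + (size_t)TB * co;
    double s = 0.0;
    for (int i = 0; i < TB; ++i) s += (double)gc[i];
    db[co] = s;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix conv1d_fwd_cpp(const NumericMatrix &X, const NumericVector &W,
                             const NumericVector &bias, int T, int B, int k,
                             int pad_mode) {
  const int TB = T * B;
  const int Ci = X.ncol();
  const int Co = bias.size();
  if (X.nrow() != TB) stop("conv1d: X rows != T*B");
  if ((int)W.size() != k * Ci * Co) stop("conv1d: weight size mismatch");
  std::vector<float> Xf((size_t)TB * Ci), Y((size_t)TB * Co);
  to_float(&X[0], Xf.data(), Xf.size());
  conv_core_fwd(Xf.data(), &W[0], Y.data(), T, B, Ci, Co, k, pad_mode);
  NumericMatrix out(TB, Co);
  for (int co = 0; co < Co; ++co) {
    const float *yc = Y.data() + (size_t)TB * co;
    double *oc = &out[0] + (size_t)TB * co;
    const double bc = bias[co];
    for (int i = 0; i < TB; ++i) oc[i] = (double)yc[i] + bc;
  }
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const NumericMatrix &X, const NumericVector &W,
                    const NumericMatrix &dY, int T, int B, int k,
                    int pad_mode) {
  const int TB = T * B;
  const int Ci = X.ncol();
  const int Co = dY.ncol();
  if (dY.nrow() != TB) stop("conv1d: dY rows != T*B");
  std::vector<float> Xf((size_t)TB * Ci), dYf((size_t)TB * Co),
      dXf((size_t)TB * Ci);
  to_float(&X[0], Xf.data(), Xf.size());
  to_float(&dY[0], dYf.data(), dYf.size());
  NumericVector dW(k * Ci * Co), db(Co);
  conv_core_bwd(Xf.data(), &W[0], dYf.data(), dXf.data(), &dW[0], &db[0], T,
                B, Ci, Co, k, pad_mode);
  NumericMatrix dX(TB, Ci);
  for (size_t i = 0; i < (size_t)TB * Ci; ++i) dX[i] = (double)dXf[i];
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Batch normalization, one C++ pass per direction.  Training mode uses
// batch statistics (biased variance for normalization, unbiased for the
// running update); inference mode uses the running statistics.
// [[Rcpp::export]]
List bn_fwd_cpp(const NumericMatrix &X, const NumericVector &gamma,
                const NumericVector &beta, const NumericVector &running_mean,
                const NumericVector &running_var, double eps, double momentum,
                bool train) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  NumericVector mu(C), inv(C), rm = clone(running_mean),
      rv = clone(running_var);
  for (int c = 0; c < C; ++c) {
    const double *xc = &X[0] + (size_t)n * c;
    double m, v;
    if (train) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += xc[i];
      m = s / n;
      double s2 = 0;
      for (int i = 0; i < n; ++i) { const double d = xc[i] - m; s2 += d * d; }
      v = s2 / n;
      rm[c] = (1 - momentum) * rm[c] + momentum * m;
      rv[c] = (1 - momentum) * rv[c] + momentum * v * n / std::max(1, n - 1);
    } else {
      m = running_mean[c];
      v = running_var[c];
    }
    const double ic = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    inv[c] = ic;
    const double g = gamma[c] * ic, b = beta[c] - gamma[c] * ic * m;
    double *yc = &Y[0] + (size_t)n * c;
    for (int i = 0; i < n; ++i) yc[i] = g * xc[i] + b;
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["inv"] = inv,
                      _["running_mean"] = rm, _["running_var"] = rv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericMatrix &X, const NumericMatrix &dY,
                const NumericVector &gamma, const NumericVector &mu,
                const NumericVector &inv, bool train) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *xc = &X[0] + (size_t)n * c;
    const double *gc = &dY[0] + (size_t)n * c;
    double *oc = &dX[0] + (size_t)n * c;
    const double m = mu[c], ic = inv[c];
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      sb += gc[i];
      sg += gc[i] * (xc[i] - m) * ic;
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double gi = gamma[c] * ic;
    if (train) {
      const double mdy = sb / n, mdyx = sg / n;
      for (int i = 0; i < n; ++i)
        oc[i] = gi * (gc[i] - mdy - (xc[i] - m) * ic * mdyx);
    } else {
      for (int i = 0; i < n; ++i) oc[i] = gi * gc[i];
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix leaky_fwd_cpp(const NumericMatrix &X, double slope) {
  const size_t n = (size_t)X.nrow() * X.ncol();
  NumericMatrix Y(X.nrow(), X.ncol());
  for (size_t i = 0; i < n; ++i)
    Y[i] = X[i] > 0 ? X[i] : slope * X[i];
  return Y;
}

// [[Rcpp::export]]
NumericMatrix leaky_bwd_cpp(const NumericMatrix &X, const NumericMatrix &dY,
                            double slope) {
  const size_t n = (size_t)X.nrow() * X.ncol();
  NumericMatrix dX(X.nrow(), X.ncol());
  for (size_t i = 0; i < n; ++i)
    dX[i] = X[i] > 0 ? dY[i] : slope * dY[i];
  return dX;
}

// ---------------------------------------------------------------------
// Fused conv -> batch-norm [-> leaky ReLU] with float caches.
//
// One call runs the convolution, batch normalization and (optionally) the
// activation in single precision, returning the double output plus an
// external pointer holding the float caches needed by the fused backward.
// This removes most intermediate double buffers from the residual blocks.

struct FusedCache {
  std::vector<float> Xf;   // conv input
  std::vector<float> A;    // conv output (pre-BN)
  std::vector<double> mu, inv;
  int T, B, Ci, Co, k, pad_mode;
  bool train, act;
  double slope;
};

// [[Rcpp::export]]
List fused_cba_fwd(const NumericMatrix &X, const NumericVector &W,
                   const NumericVector &bias, int T, int B, int k,
                   int pad_mode, const NumericVector &gamma,
                   const NumericVector &beta,
                   const NumericVector &running_mean,
                   const NumericVector &running_var, double eps,
                   double momentum, bool train, bool act, double slope) {
  const int TB = T * B;
  const int Ci = X.ncol();
  const int Co = gamma.size();
  if (X.nrow() != TB) stop("fused: X rows != T*B");

  XPtr<FusedCache> cache(new FusedCache(), true);
  cache->Xf.resize((size_t)TB * Ci);
  cache->A.resize((size_t)TB * Co);
  cache->mu.resize(Co);
  cache->inv.resize(Co);
  cache->T = T; cache->B = B; cache->Ci = Ci; cache->Co = Co; cache->k = k;
  cache->pad_mode = pad_mode; cache->train = train; cache->act = act;
  cache->slope = slope;

  to_float(&X[0], cache->Xf.data(), cache->Xf.size());
  conv_core_fwd(cache->Xf.data(), &W[0], cache->A.data(), T, B, Ci, Co, k,
                pad_mode);
  // conv bias folds into the BN input
  for (int co = 0; co < Co; ++co) {
    float *ac = cache->A.data() + (size_t)TB * co;
    const float bc = (float)bias[co];
    if (bc != 0.0f) for (int i = 0; i < TB; ++i) ac[i] += bc;
  }

  NumericMatrix Y(TB, Co);
  NumericVector rm = clone(running_mean), rv = clone(running_var);
  for (int co = 0; co < Co; ++co) {
    const float *ac = cache->A.data() + (size_t)TB * co;
    double m, v;
    if (train) {
      double s = 0;
      for (int i = 0; i < TB; ++i) s += ac[i];
      m = s / TB;
      double s2 = 0;
      for (int i = 0; i < TB; ++i) { const double d = ac[i] - m; s2 += d * d; }
      v = s2 / TB;
      rm[co] = (1 - momentum) * rm[co] + momentum * m;
      rv[co] = (1 - momentum) * rv[co] + momentum * v * TB / std::max(1, TB - 1);
    } else {
      m = running_mean[co];
      v = running_var[co];
    }
    const double ic = 1.0 / std::sqrt(v + eps);
    cache->mu[co] = m;
    cache->inv[co] = ic;
    const double g = gamma[co] * ic, b = beta[co] - gamma[co] * ic * m;
    double *yc = &Y[0] + (size_t)TB * co;
    if (act) {
      for (int i = 0; i < TB; ++i) {
        const double y = g * ac[i] + b;
        yc[i] = y > 0 ? y : slope * y;
      }
    } else {
      for (int i = 0; i < TB; ++i) yc[i] = g * ac[i] + b;
    }
  }
  return List::create(_["Y"] = Y, _["cache"] = cache,
                      _["running_mean"] = rm, _["running_var"] = rv);
}

// [[Rcpp::export]]
List fused_cba_bwd(SEXP cache_ptr, const NumericVector &W,
                   const NumericVector &gamma, const NumericVector &beta,
                   const NumericMatrix &dY) {
  XPtr<FusedCache> cache(cache_ptr);
  const int T = cache->T, B = cache->B, Ci = cache->Ci, Co = cache->Co;
  const int TB = T * B;
  if (dY.nrow() != TB || dY.ncol() != Co) stop("fused bwd: dY shape");

  std::vector<float> dA((size_t)TB * Co);
  NumericVector dgamma(Co), dbeta(Co);
  for (int co = 0; co < Co; ++co) {
    const float *ac = cache->A.data() + (size_t)TB * co;
    const double *gy = &dY[0] + (size_t)TB * co;
    float *dac = dA.data() + (size_t)TB * co;
    const double m = cache->mu[co], ic = cache->inv[co];
    const double g = gamma[co] * ic, b = beta[co] - gamma[co] * ic * m;
    // backward through activation (recompute BN output sign), then BN
    double sg = 0, sb = 0;
    for (int i = 0; i < TB; ++i) {
      double d = gy[i];
      if (cache->act) {
        const double y = g * ac[i] + b;
        if (y <= 0) d *= cache->slope;
      }
      sb += d;
      sg += d * (ac[i] - m) * ic;
      dac[i] = (float)d;  // temporarily holds post-activation gradient
    }
    dgamma[co] = sg;
    dbeta[co] = sb;
    const double gi = gamma[co] * ic;
    if (cache->train) {
      const double mdy = sb / TB, mdyx = sg / TB;
      for (int i = 0; i < TB; ++i)
        dac[i] = (float)(gi * (dac[i] - mdy - (ac[i] - m) * ic * mdyx));
    } else {
      for (int i = 0; i < TB; ++i) dac[i] = (float)(gi * dac[i]);
    }
  }

  NumericVector dW(cache->k * Ci * Co), db(Co);
  std::vector<float> dXf((size_t)TB * Ci);
  conv_core_bwd(cache->Xf.data(), &W[0], dA.data(), dXf.data(), &dW[0],
                &db[0], T, B, Ci, Co, cache->k, cache->pad_mode);
  NumericMatrix dX(TB, Ci);
  for (size_t i = 0; i < (size_t)TB * Ci; ++i) dX[i] = (double)dXf[i];
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
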