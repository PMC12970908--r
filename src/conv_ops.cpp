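// Convolution and batch-normalization kernels for the autodiff engine.
//
// Feature maps are channels-last (N, H, W, C), column-major. Convolutions
// are same-padded, stride 1, realized as im2col + BLAS dgemm. The im2col
// buffers live in a workspace that persists across calls and is recomputed
// in the backward pass, so the tape never retains them and the R heap sees
// no large short-lived allocations (which are disproportionately expensive
// on virtualized hosts).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

static std::vector<double> ws_col;  // im2col buffer
static std::vector<double> ws_gcol; // column-gradient buffer

// Raise glibc's mmap threshold to its maximum and disable heap trimming so
// large buffers are reused instead of being returned to (and re-faulted
// from) the kernel on every step.
// [[Rcpp::export]]
void cpp_tune_malloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 32 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// im2col for channels [c0, c0+cg) into `col` (rows x cg*k*k, column-major,
// channel fastest within each offset). For a fixed offset/channel/output
// column the valid h-range is one contiguous span of the source.
static void im2col_group(const double* xp, double* col, int N, int H, int W,
                         int C, int k, int c0, int cg) {
  const int p = (k - 1) / 2;
  const size_t rows = (size_t)N * H * W;
  for (int o = 0; o < k * k; ++o) {
    const int dy = o % k - p;
    const int dx = o / k - p;
    const int h_lo = std::max(0, -dy), h_hi = std::min(H, H - dy);
    for (int c = 0; c < cg; ++c) {
      double* cp = col + (size_t)(c + cg * o) * rows;
      const double* chan = xp + (size_t)N * H * W * (c0 + c);
      for (int w = 0; w < W; ++w) {
        const int sw = w + dx;
        double* dst = cp + (size_t)N * H * w;
        if (sw < 0 || sw >= W) {
          std::memset(dst, 0, sizeof(double) * (size_t)N * H);
          continue;
        }
        if (h_lo > 0) std::memset(dst, 0, sizeof(double) * (size_t)N * h_lo);
        if (h_hi < H)
          std::memset(dst + (size_t)N * h_hi, 0,
                      sizeof(double) * (size_t)N * (H - h_hi));
        if (h_hi > h_lo)
          std::memcpy(dst + (size_t)N * h_lo,
                      chan + (size_t)N * (h_lo + dy + H * sw),
                      sizeof(double) * (size_t)N * (h_hi - h_lo));
      }
    }
  }
}

// adjoint of im2col_group: scatter-add `col` into channels [c0, c0+cg)
static void col2im_group(const double* col, double* xp, int N, int H, int W,
                         int C, int k, int c0, int cg) {
  const int p = (k - 1) / 2;
  const size_t rows = (size_t)N * H * W;
  for (int o = 0; o < k * k; ++o) {
    const int dy = o % k - p;
    const int dx = o / k - p;
    const int h_lo = std::max(0, -dy), h_hi = std::min(H, H - dy);
    if (h_hi <= h_lo) continue;
    const size_t span = (size_t)N * (h_hi - h_lo);
    for (int c = 0; c < cg; ++c) {
      const double* cp = col + (size_t)(c + cg * o) * rows;
      double* chan = xp + (size_t)N * H * W * (c0 + c);
      for (int w = 0; w < W; ++w) {
        const int sw = w + dx;
        if (sw < 0 || sw >= W) continue;
        const double* src = cp + (size_t)N * (h_lo + H * w);
        double* dst = chan + (size_t)N * (h_lo + dy + H * sw);
        for (size_t i = 0; i < span; ++i) dst[i] += src[i];
      }
    }
  }
}

static void dgemm_(char ta, char tb, int m, int n, int kk, double alpha,
                   const double* A, int lda, const double* B, int ldb,
                   double beta, double* Cm, int ldc) {
  char tac[2] = {ta, 0}, tbc[2] = {tb, 0};
  F77_CALL(dgemm)(tac, tbc, &m, &n, &kk, &alpha, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, Cm, &ldc FCONE FCONE);
}

// Grouped convolution forward: x (N,H,W,C), w ((C/groups)*k^2 x Cout).
// Returns (N,H,W,Cout).
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix w, int N, int H,
                           int W, int C, int k, int groups) {
  const int cg = C / groups;
  const int Cout = w.ncol();
  const int cog = Cout / groups;
  const int K = cg * k * k;
  const size_t rows = (size_t)N * H * W;
  NumericVector y(no_init(rows * Cout));
  y.attr("dim") = IntegerVector::create(N, H, W, Cout);
  if (ws_col.size() < rows * K) ws_col.resize(rows * K);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), ws_col.data(), N, H, W, C, k, g * cg, cg);
    dgemm_('N', 'N', (int)rows, cog, K, 1.0, ws_col.data(), (int)rows,
           w.begin() + (size_t)K * cog * g, K, 0.0,
           y.begin() + rows * cog * g, (int)rows);
  }
  return y;
}

// Grouped convolution backward. gy is the (N,H,W,Cout) output gradient;
// recomputes im2col from x. Returns gw and (if need_gx) gx.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix w, NumericVector gy, int N,
                  int H, int W, int C, int k, int groups, bool need_gx) {
  const int cg = C / groups;
  const int Cout = w.ncol();
  const int cog = Cout / groups;
  const int K = cg * k * k;
  const size_t rows = (size_t)N * H * W;
  NumericMatrix gw(K, Cout);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(rows * C); // zero-initialized: col2im accumulates
    gx.attr("dim") = IntegerVector::create(N, H, W, C);
  }
  if (ws_col.size() < rows * K) ws_col.resize(rows * K);
  if (need_gx && ws_gcol.size() < rows * K) ws_gcol.resize(rows * K);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), ws_col.data(), N, H, W, C, k, g * cg, cg);
    // gw_g = col^T (K x rows) * gy_g (rows x cog)
    dgemm_('T', 'N', K, cog, (int)rows, 1.0, ws_col.data(), (int)rows,
           gy.begin() + rows * cog * g, (int)rows, 0.0,
           gw.begin() + (size_t)K * cog * g, K);
    if (need_gx) {
      // gcol = gy_g (rows x cog) * w_g^T (cog x K)
      dgemm_('N', 'T', (int)rows, K, cog, 1.0, gy.begin() + rows * cog * g,
             (int)rows, w.begin() + (size_t)K * cog * g, K, 0.0,
             ws_gcol.data(), (int)rows);
      col2im_group(ws_gcol.data(), gx.begin(), N, H, W, C, k, g * cg, cg);
    }
  }
  return need_gx ? List::create(_["gw"] = gw, _["gx"] = gx)
                 : List::create(_["gw"] = gw);
}

// Batch-normalization forward on the (M x C) view of a channels-last array.
// In training mode computes batch statistics; returns y, xhat and the
// statistics used.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, int M, int C, NumericVector run_mean,
                NumericVector run_var, NumericVector gamma,
                NumericVector beta, bool training, double eps) {
  NumericVector y(no_init(x.size())), xhat(no_init(x.size()));
  NumericVector mean(C), sd(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double mu, va;
    const double* xc = xp + (size_t)M * c;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < M; ++i) {
        s += xc[i];
        s2 += xc[i] * xc[i];
      }
      mu = s / M;
      va = s2 / M - mu * mu;
      if (va < 0) va = 0;
    } else {
      mu = run_mean[c];
      va = run_var[c];
    }
    mean[c] = mu;
    var[c] = va;
    const double s = std::sqrt(va + eps);
    sd[c] = s;
    const double g = gamma[c], b = beta[c];
    double* yc = y.begin() + (size_t)M * c;
    double* hc = xhat.begin() + (size_t)M * c;
    for (int i = 0; i < M; ++i) {
      const double h = (xc[i] - mu) / s;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["var"] = var, _["sd"] = sd);
}

// Batch-normalization backward (training formula includes the gradient of
// the batch statistics).
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, int M, int C,
                NumericVector gamma, NumericVector sd, bool training) {
  NumericVector gx(no_init(gy.size())), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + (size_t)M * c;
    const double* hc = xhat.begin() + (size_t)M * c;
    double* oc = gx.begin() + (size_t)M * c;
    double sg = 0.0, sgh = 0.0;
    for (int i = 0; i < M; ++i) {
      sg += gc[i];
      sgh += gc[i] * hc[i];
    }
    dbeta[c] = sg;
    dgamma[c] = sgh;
    const double gs = gamma[c] / sd[c];
    if (training) {
      const double m1 = sg / M, m2 = sgh / M;
      for (int i = 0; i < M; ++i) oc[i] = gs * (gc[i] - m1 - hc[i] * m2);
    } else {
      for (int i = 0; i < M; ++i) oc[i] = gs * gc[i];
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// mean over H, W: (N,H,W,C) -> (N,C)
// [[Rcpp::export]]
NumericMatrix cpp_mean_hw(NumericVector x, int N, int H, int W, int C) {
  NumericMatrix out(N, C);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)N * HW * c;
    double* oc = out.begin() + (size_t)N * c;
    for (int j = 0; j < HW; ++j) {
      const double* col = xc + (size_t)N * j;
      for (int n = 0; n < N; ++n) oc[n] += col[n];
    }
    for (int n = 0; n < N; ++n) oc[n] /= HW;
  }
  return out;
}

// broadcast (N,C) over H, W with scaling: out[n,h,w,c] = g[n,c] * s
// [[Rcpp::export]]
NumericVector cpp_broadcast_hw(NumericMatrix g, int N, int H, int W, int C,
                               double s) {
  NumericVector out(no_init((size_t)N * H * W * C));
  out.attr("dim") = IntegerVector::create(N, H, W, C);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* gc = g.begin() + (size_t)N * c;
    double* oc = out.begin() + (size_t)N * HW * c;
    for (int j = 0; j < HW; ++j) {
      double* col = oc + (size_t)N * j;
      for (int n = 0; n < N; ++n) col[n] = gc[n] * s;
    }
  }
  return out;
}

// per-channel gating forward: y[n,h,w,c] = x[n,h,w,c] * g[n,c]
// [[Rcpp::export]]
NumericVector cpp_scale_channels_fwd(NumericVector x, NumericMatrix g, int N,
                                     int H, int W, int C) {
  NumericVector out(no_init(x.size()));
  out.attr("dim") = IntegerVector::create(N, H, W, C);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* gc = g.begin() + (size_t)N * c;
    const double* xc = x.begin() + (size_t)N * HW * c;
    double* oc = out.begin() + (size_t)N * HW * c;
    for (int j = 0; j < HW; ++j) {
      const double* xcol = xc + (size_t)N * j;
      double* ocol = oc + (size_t)N * j;
      for (int n = 0; n < N; ++n) ocol[n] = xcol[n] * gc[n];
    }
  }
  return out;
}

// gating backward: gx = gy * g (broadcast), dgate[n,c] = sum_hw gy * x
// [[Rcpp::export]]
List cpp_scale_channels_bwd(NumericVector x, NumericMatrix g,
                            NumericVector gy, int N, int H, int W, int C) {
  NumericVector gx(no_init(x.size()));
  gx.attr("dim") = IntegerVector::create(N, H, W, C);
  NumericMatrix dg(N, C);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* gc = g.begin() + (size_t)N * c;
    const double* xc = x.begin() + (size_t)N * HW * c;
    const double* yc = gy.begin() + (size_t)N * HW * c;
    double* oc = gx.begin() + (size_t)N * HW * c;
    double* dc = dg.begin() + (size_t)N * c;
    for (int j = 0; j < HW; ++j) {
      const size_t off = (size_t)N * j;
      for (int n = 0; n < N; ++n) {
        oc[off + n] = yc[off + n] * gc[n];
        dc[n] += yc[off + n] * xc[off + n];
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgate"] = dg);
}
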