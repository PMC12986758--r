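// Fused kernels for the memory-bound layers of the network. Tensors use the
// internal (B, T, N, C) column-major layout; BLAS-backed matrix products stay
// on the R side, these kernels cover the padded dilated temporal convolution,
// batch normalization and elementwise fusions where R's generic array
// subsetting dominates the run time.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// C += A (M x K, lda) * B (K x N), accumulating into C (M x N, ldc).
static void dgemm_acc(const double* A, int lda, const double* B, int K,
                      double* C, int ldc, int M, int N, double beta) {
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &M, &N, &K, &one, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &K, &beta, C, &ldc
                  FCONE FCONE);
}

// Copy the (B, T, N, C) tensor into a (B, T + 2p, N, C) zero-padded buffer.
static std::vector<double> pad_time(const double* xp, int B, int T, int N,
                                    int C, int p) {
  const int Tp = T + 2 * p;
  std::vector<double> out(static_cast<size_t>(B) * Tp * N * C, 0.0);
  const R_xlen_t planeX = static_cast<R_xlen_t>(B) * T * N;
  const R_xlen_t planeP = static_cast<R_xlen_t>(B) * Tp * N;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* src = xp + planeX * c + static_cast<R_xlen_t>(n) * B * T;
      double* dst = out.data() + planeP * c +
        static_cast<R_xlen_t>(n) * B * Tp + static_cast<R_xlen_t>(p) * B;
      std::copy(src, src + static_cast<R_xlen_t>(B) * T, dst);
    }
  }
  return out;
}

// y[b,t,n,co] = bias[co] + sum_{j,ci} x[b, t + j*dil - p, n, ci] * K[ci,co,j]
// with zero padding outside [0, T). In the padded layout every tap is a
// constant row shift, so each tap is one accumulating BLAS gemm.
// [[Rcpp::export]]
NumericVector cpp_tconv_fwd(const NumericVector& x, const IntegerVector& dims,
                            const NumericVector& K, int cin, int cout,
                            int kern, const NumericVector& bias, int dil) {
  const int B = dims[0], T = dims[1], N = dims[2];
  const int p = dil * (kern - 1) / 2;
  const int Tp = T + 2 * p;
  const R_xlen_t planeX = static_cast<R_xlen_t>(B) * T * N;
  const R_xlen_t planeP = static_cast<R_xlen_t>(B) * Tp * N;
  std::vector<double> xpad = pad_time(x.begin(), B, T, N, cin, p);
  std::vector<double> ypad(static_cast<size_t>(planeP) * cout, 0.0);
  const double* Kp = K.begin();
  for (int j = 0; j < kern; ++j) {
    const R_xlen_t shift = static_cast<R_xlen_t>(B) * (j * dil - p);
    const R_xlen_t r0 = std::max<R_xlen_t>(0, -shift);
    const int M = static_cast<int>(planeP - std::llabs(shift));
    if (M <= 0) continue;
    dgemm_acc(xpad.data() + r0 + shift, static_cast<int>(planeP),
              Kp + static_cast<R_xlen_t>(cin) * cout * j, cin,
              ypad.data() + r0, static_cast<int>(planeP), M, cout, 1.0);
  }
  NumericVector y(planeX * cout);
  double* yp = y.begin();
  for (int co = 0; co < cout; ++co) {
    const double bv = bias[co];
    for (int n = 0; n < N; ++n) {
      const double* src = ypad.data() + planeP * co +
        static_cast<R_xlen_t>(n) * B * Tp + static_cast<R_xlen_t>(p) * B;
      double* dst = yp + planeX * co + static_cast<R_xlen_t>(n) * B * T;
      const R_xlen_t len = static_cast<R_xlen_t>(B) * T;
      for (R_xlen_t i = 0; i < len; ++i) dst[i] = src[i] + bv;
    }
  }
  return y;
}

// Backward of cpp_tconv_fwd: returns dX; fills dK (cin x cout x kern) and
// db (cout) in place.
// [[Rcpp::export]]
NumericVector cpp_tconv_bwd(const NumericVector& x, const NumericVector& dy,
                            const IntegerVector& dims, const NumericVector& K,
                            int cin, int cout, int kern, int dil,
                            NumericVector dK, NumericVector db) {
  const int B = dims[0], T = dims[1], N = dims[2];
  const int p = dil * (kern - 1) / 2;
  const int Tp = T + 2 * p;
  const R_xlen_t planeX = static_cast<R_xlen_t>(B) * T * N;
  const R_xlen_t planeP = static_cast<R_xlen_t>(B) * Tp * N;
  std::vector<double> xpad = pad_time(x.begin(), B, T, N, cin, p);
  std::vector<double> dypad = pad_time(dy.begin(), B, T, N, cout, p);
  std::vector<double> dxpad(static_cast<size_t>(planeP) * cin, 0.0);
  const double* Kp = K.begin();
  const double* dyp = dy.begin();
  for (int co = 0; co < cout; ++co) {
    const double* dyc = dyp + planeX * co;
    double s = 0.0;
    for (R_xlen_t i = 0; i < planeX; ++i) s += dyc[i];
    db[co] = s;
  }
  const double one = 1.0, zero = 0.0;
  const int planePi = static_cast<int>(planeP);
  for (int j = 0; j < kern; ++j) {
    const R_xlen_t shift = static_cast<R_xlen_t>(B) * (j * dil - p);
    const R_xlen_t r0 = std::max<R_xlen_t>(0, -shift);
    const int M = static_cast<int>(planeP - std::llabs(shift));
    if (M <= 0) continue;
    // dK_j = xpad_shifted^T * dypad
    F77_CALL(dgemm)("T", "N", &cin, &cout, &M, &one,
                    const_cast<double*>(xpad.data() + r0 + shift), &planePi,
                    dypad.data() + r0, &planePi, &zero,
                    dK.begin() + static_cast<R_xlen_t>(cin) * cout * j, &cin
                    FCONE FCONE);
    // dxpad_shifted += dypad * K_j^T
    F77_CALL(dgemm)("N", "T", &M, &cin, &cout, &one,
                    dypad.data() + r0, &planePi,
                    const_cast<double*>(Kp + static_cast<R_xlen_t>(cin) * cout * j),
                    &cin, &one, dxpad.data() + r0 + shift, &planePi
                    FCONE FCONE);
  }
  NumericVector dx(planeX * cin);
  double* dxp = dx.begin();
  for (int ci = 0; ci < cin; ++ci) {
    for (int n = 0; n < N; ++n) {
      const double* src = dxpad.data() + planeP * ci +
        static_cast<R_xlen_t>(n) * B * Tp + static_cast<R_xlen_t>(p) * B;
      double* dst = dxp + planeX * ci + static_cast<R_xlen_t>(n) * B * T;
      std::copy(src, src + static_cast<R_xlen_t>(B) * T, dst);
    }
  }
  return dx;
}

// Fused batch-norm forward on an (M x C) matrix view: returns normalized
// output, writes xhat into the supplied buffer.
// [[Rcpp::export]]
NumericVector cpp_bn_apply(const NumericVector& x, int M, int C,
                           const NumericVector& mu, const NumericVector& inv_std,
                           const NumericVector& gamma, const NumericVector& beta,
                           NumericVector xhat) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = inv_std[c], g = gamma[c], b = beta[c];
    const double* xs = xp + static_cast<R_xlen_t>(M) * c;
    double* ys = yp + static_cast<R_xlen_t>(M) * c;
    double* hs = hp + static_cast<R_xlen_t>(M) * c;
    for (int i = 0; i < M; ++i) {
      const double h = (xs[i] - m) * is;
      hs[i] = h;
      ys[i] = h * g + b;
    }
  }
  return y;
}

// Fused batch-norm backward (training mode): returns dX and fills
// dgamma/dbeta in place.
// [[Rcpp::export]]
NumericVector cpp_bn_bwd(const NumericVector& dy, const NumericVector& xhat,
                         int M, int C, const NumericVector& inv_std,
                         const NumericVector& gamma, bool training,
                         NumericVector dgamma, NumericVector dbeta) {
  NumericVector dx(dy.size());
  const double* dyp = dy.begin();
  const double* hp = xhat.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dys = dyp + static_cast<R_xlen_t>(M) * c;
    const double* hs = hp + static_cast<R_xlen_t>(M) * c;
    double* dxs = dxp + static_cast<R_xlen_t>(M) * c;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < M; ++i) {
      sg += dys[i] * hs[i];
      sb += dys[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = inv_std[c];
    if (training) {
      const double m1 = sb / M, m2 = sg / M;
      for (int i = 0; i < M; ++i) {
        dxs[i] = (dys[i] * g - g * m1 - hs[i] * g * m2) * is;
      }
    } else {
      for (int i = 0; i < M; ++i) dxs[i] = dys[i] * g * is;
    }
  }
  return dx;
}

// Column means and biased variances of an (M x C) matrix view in one pass.
// [[Rcpp::export]]
List cpp_colstats(const NumericVector& x, int M, int C) {
  NumericVector mu(C), v(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xs = xp + static_cast<R_xlen_t>(M) * c;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < M; ++i) {
      s += xs[i];
      s2 += xs[i] * xs[i];
    }
    const double m = s / M;
    mu[c] = m;
    v[c] = s2 / M - m * m;
    if (v[c] < 0) v[c] = 0;
  }
  return List::create(Named("mean") = mu, Named("var") = v);
}

// In-place column-wise bias add on an (M x C) matrix view.
// [[Rcpp::export]]
void cpp_add_bias(NumericVector y, int M, int C, const NumericVector& bias) {
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double b = bias[c];
    double* ys = yp + static_cast<R_xlen_t>(M) * c;
    for (int i = 0; i < M; ++i) ys[i] += b;
  }
}

// ReLU forward returning output; mask is recoverable as (out > 0) but the
// backward below uses the stored output directly.
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(const NumericVector& x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// ReLU backward using the forward output (y > 0 <=> x > 0).
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(const NumericVector& dy, const NumericVector& y) {
  NumericVector dx(dy.size());
  const double* dyp = dy.begin();
  const double* yp = y.begin();
  double* dxp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[i] = yp[i] > 0 ? dyp[i] : 0.0;
  return dx;
}

// Write a node-major (B,T,C,N) buffer into channel block k of the
// concatenated (B,T,N,K*C) output.
// [[Rcpp::export]]
void cpp_write_block(NumericVector out, const NumericVector& src,
                     const IntegerVector& dims, int k, int K) {
  const int d1 = dims[0], d2 = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t bt = static_cast<R_xlen_t>(d1) * d2;
  double* op = out.begin();
  const double* sp = src.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* ss = sp + bt * (c + static_cast<R_xlen_t>(C) * n);
      double* os = op + bt * (n + static_cast<R_xlen_t>(N) *
                              (static_cast<R_xlen_t>(k) * C + c));
      std::copy(ss, ss + bt, os);
    }
  }
}

// Read channel block k of a (B,T,N,K*C) tensor into node-major (B,T,C,N).
// [[Rcpp::export]]
NumericVector cpp_read_block(const NumericVector& x,
                             const IntegerVector& dims, int k, int K) {
  const int d1 = dims[0], d2 = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t bt = static_cast<R_xlen_t>(d1) * d2;
  NumericVector y(bt * N * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + bt * (n + static_cast<R_xlen_t>(N) *
                                    (static_cast<R_xlen_t>(k) * C + c));
      double* ys = yp + bt * (c + static_cast<R_xlen_t>(C) * n);
      std::copy(xs, xs + bt, ys);
    }
  }
  return y;
}

// Collapse the three tiled frames with per-channel weights:
// y[m, n, c] = b[c] + sum_f A[f, c] * z[m, n, f, c], m over (B*T).
// [[Rcpp::export]]
NumericVector cpp_tau_collapse_fwd(const NumericVector& z, int M, int N,
                                   int C, const NumericVector& A,
                                   const NumericVector& b) {
  NumericVector y(static_cast<R_xlen_t>(M) * N * C);
  const double* zp = z.begin();
  double* yp = y.begin();
  const R_xlen_t slab = static_cast<R_xlen_t>(M) * N;
  for (int c = 0; c < C; ++c) {
    double* ys = yp + slab * c;
    const double bc = b[c];
    for (R_xlen_t i = 0; i < slab; ++i) ys[i] = bc;
    for (int f = 0; f < 3; ++f) {
      const double w = A[f + 3 * c];
      const double* zs = zp + slab * (f + 3 * static_cast<R_xlen_t>(c));
      for (R_xlen_t i = 0; i < slab; ++i) ys[i] += w * zs[i];
    }
  }
  return y;
}

// Backward of the tau collapse; fills dA (3 x C) and db (C) in place.
// [[Rcpp::export]]
NumericVector cpp_tau_collapse_bwd(const NumericVector& dy,
                                   const NumericVector& z, int M, int N,
                                   int C, const NumericVector& A,
                                   NumericVector dA, NumericVector db) {
  NumericVector dz(z.size());
  const double* dyp = dy.begin();
  const double* zp = z.begin();
  double* dzp = dz.begin();
  const R_xlen_t slab = static_cast<R_xlen_t>(M) * N;
  for (int c = 0; c < C; ++c) {
    const double* dys = dyp + slab * c;
    double sb = 0.0;
    for (R_xlen_t i = 0; i < slab; ++i) sb += dys[i];
    db[c] = sb;
    for (int f = 0; f < 3; ++f) {
      const double w = A[f + 3 * c];
      const double* zs = zp + slab * (f + 3 * static_cast<R_xlen_t>(c));
      double* dzs = dzp + slab * (f + 3 * static_cast<R_xlen_t>(c));
      double acc = 0.0;
      for (R_xlen_t i = 0; i < slab; ++i) {
        acc += dys[i] * zs[i];
        dzs[i] = w * dys[i];
      }
      dA[f + 3 * c] = acc;
    }
  }
  return dz;
}

// Unfold (B,T,N,C) into three time-shifted frames along the node axis:
// out (B,T,3N,C); frame 1 = t-1, frame 2 = t, frame 3 = t+1 (zero padded).
// [[Rcpp::export]]
NumericVector cpp_unfold3_fwd(const NumericVector& x,
                              const IntegerVector& dims) {
  const int B = dims[0], T = dims[1], N = dims[2], C = dims[3];
  NumericVector y(static_cast<R_xlen_t>(B) * T * 3 * N * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t planeX = static_cast<R_xlen_t>(B) * T * N;
  const R_xlen_t planeY = planeX * 3;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + planeX * c + static_cast<R_xlen_t>(n) * B * T;
      double* y1 = yp + planeY * c + static_cast<R_xlen_t>(n) * B * T;
      double* y2 = y1 + static_cast<R_xlen_t>(N) * B * T;
      double* y3 = y2 + static_cast<R_xlen_t>(N) * B * T;
      // frame 2: centre
      std::copy(xs, xs + static_cast<R_xlen_t>(B) * T, y2);
      // frame 1: previous frame (dest t >= 1)
      std::copy(xs, xs + static_cast<R_xlen_t>(B) * (T - 1), y1 + B);
      // frame 3: next frame (dest t <= T-2)
      std::copy(xs + B, xs + static_cast<R_xlen_t>(B) * T, y3);
    }
  }
  return y;
}

// Backward of the unfold: scatter-add the three frames back.
// [[Rcpp::export]]
NumericVector cpp_unfold3_bwd(const NumericVector& dy,
                              const IntegerVector& dims) {
  const int B = dims[0], T = dims[1], N = dims[2], C = dims[3];
  NumericVector dx(static_cast<R_xlen_t>(B) * T * N * C);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const R_xlen_t planeX = static_cast<R_xlen_t>(B) * T * N;
  const R_xlen_t planeY = planeX * 3;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      double* dxs = dxp + planeX * c + static_cast<R_xlen_t>(n) * B * T;
      const double* y1 = dyp + planeY * c + static_cast<R_xlen_t>(n) * B * T;
      const double* y2 = y1 + static_cast<R_xlen_t>(N) * B * T;
      const double* y3 = y2 + static_cast<R_xlen_t>(N) * B * T;
      const R_xlen_t len = static_cast<R_xlen_t>(B) * T;
      for (R_xlen_t i = 0; i < len; ++i) dxs[i] = y2[i];
      for (R_xlen_t i = 0; i < len - B; ++i) dxs[i] += y1[i + B];
      for (R_xlen_t i = B; i < len; ++i) dxs[i] += y3[i - B];
    }
  }
  return dx;
}

// Expand raw segments (B, 1, w, N) into sliding sub-window Fisher-z
// connectivity frames (B, Tp, N, N), Tp = w - w2 + 1. Zero-variance columns
// give zero correlation; |r| is clipped below 1 before atanh.
// [[Rcpp::export]]
NumericVector cpp_dfc_expand(const NumericVector& x, const IntegerVector& dims,
                             int w2) {
  const int B = dims[0], w = dims[2], N = dims[3];
  const int Tp = w - w2 + 1;
  const double eps = 1e-7;
  const double zmax = 1.0 - eps;
  NumericVector out(static_cast<R_xlen_t>(B) * Tp * N * N);
  std::vector<double> seg(static_cast<size_t>(w) * N);
  std::vector<double> zbuf(static_cast<size_t>(w2) * N);
  std::vector<double> C(static_cast<size_t>(N) * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    // gather the segment: x[b, 0, t, n] at index b + B*(t + w*n)
    for (int n = 0; n < N; ++n) {
      for (int t = 0; t < w; ++t) {
        seg[t + static_cast<size_t>(w) * n] =
          xp[b + static_cast<R_xlen_t>(B) * (t + static_cast<R_xlen_t>(w) * n)];
      }
    }
    for (int tau = 0; tau < Tp; ++tau) {
      for (int n = 0; n < N; ++n) {
        const double* col = seg.data() + static_cast<size_t>(w) * n + tau;
        double s = 0.0;
        for (int t = 0; t < w2; ++t) s += col[t];
        const double mu = s / w2;
        double ss = 0.0;
        double* zc = zbuf.data() + static_cast<size_t>(w2) * n;
        for (int t = 0; t < w2; ++t) {
          zc[t] = col[t] - mu;
          ss += zc[t] * zc[t];
        }
        const double sd = std::sqrt(ss);
        const double inv = sd < 1e-8 ? 0.0 : 1.0 / sd;
        for (int t = 0; t < w2; ++t) zc[t] *= inv;
      }
      // C = Z^T Z (N x N correlation matrix)
      F77_CALL(dgemm)("T", "N", &N, &N, &w2, &one, zbuf.data(), &w2,
                      zbuf.data(), &w2, &zero, C.data(), &N FCONE FCONE);
      for (int cc = 0; cc < N; ++cc) {
        for (int n = 0; n < N; ++n) {
          double r = C[n + static_cast<size_t>(N) * cc];
          double z;
          if (n == cc) {
            z = 0.0;
          } else {
            if (r > zmax) r = zmax;
            if (r < -zmax) r = -zmax;
            z = std::atanh(r);
          }
          // out[b, tau, n, cc]
          op[b + static_cast<R_xlen_t>(B) *
             (tau + static_cast<R_xlen_t>(Tp) *
              (n + static_cast<R_xlen_t>(N) * cc))] = z;
        }
      }
    }
  }
  return out;
}

// 4-d permutation (1,2,4,3) <-> swap of the last two axes, the only aperm the
// network needs (node-last for graph products, channel-last otherwise).
// [[Rcpp::export]]
NumericVector cpp_swap34(const NumericVector& x, const IntegerVector& dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], d4 = dims[3];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t bt = static_cast<R_xlen_t>(d1) * d2;
  for (int c = 0; c < d4; ++c) {
    for (int n = 0; n < d3; ++n) {
      const double* xs = xp + bt * (n + static_cast<R_xlen_t>(d3) * c);
      double* ys = yp + bt * (c + static_cast<R_xlen_t>(d4) * n);
      std::copy(xs, xs + bt, ys);
    }
  }
  return y;
}
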