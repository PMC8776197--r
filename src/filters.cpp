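#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Order-8 direct-form II transposed pass with named register state.
// dir = +1 reads/writes ascending, -1 descending. x and y must not alias.
static inline void pass8(const double* b, const double* a,
                         const double* __restrict__ x,
                         double* __restrict__ y, int n,
                         const double* zi, int dir) {
  const double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4],
               b5 = b[5], b6 = b[6], b7 = b[7], b8 = b[8];
  const double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4], a5 = a[5],
               a6 = a[6], a7 = a[7], a8 = a[8];
  const int i0 = dir > 0 ? 0 : n - 1;
  const double x0 = x[i0];
  double z0 = zi[0] * x0, z1 = zi[1] * x0, z2 = zi[2] * x0,
         z3 = zi[3] * x0, z4 = zi[4] * x0, z5 = zi[5] * x0,
         z6 = zi[6] * x0, z7 = zi[7] * x0;
  for (int i = 0, k = i0; i < n; ++i, k += dir) {
    const double xi = x[k];
    const double yi = b0 * xi + z0;
    z0 = b1 * xi + z1 - a1 * yi;
    z1 = b2 * xi + z2 - a2 * yi;
    z2 = b3 * xi + z3 - a3 * yi;
    z3 = b4 * xi + z4 - a4 * yi;
    z4 = b5 * xi + z5 - a5 * yi;
    z5 = b6 * xi + z6 - a6 * yi;
    z6 = b7 * xi + z7 - a7 * yi;
    z7 = b8 * xi - a8 * yi;
    y[k] = yi;
  }
}

// generic-order pass, state primed as zi * first processed sample
static void pass_gen(const double* b, const double* a, int m,
                     const double* x, double* y, int n,
                     const double* zi, int dir) {
  std::vector<double> z(m);
  const int i0 = dir > 0 ? 0 : n - 1;
  for (int j = 0; j < m; ++j) z[j] = zi[j] * x[i0];
  for (int i = 0, k = i0; i < n; ++i, k += dir) {
    const double xi = x[k];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[m - 1] = b[m] * xi - a[m] * yi;
    y[k] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of each column of X. The
// per-pass state is primed with zi (steady-state unit-step response)
// scaled by the first processed sample.
// [[Rcpp::export(name = ".iir_filtfilt_cols")]]
NumericMatrix iir_filtfilt_cols(NumericVector b, NumericVector a,
                                NumericMatrix X, NumericVector zi) {
  int m = std::max(a.size(), b.size()) - 1;
  std::vector<double> bb(m + 1, 0.0), aa(m + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (zi.size() != m) stop("zi must have length max(na, nb) - 1");

  int n = X.nrow(), k = X.ncol();
  NumericMatrix Y(n, k);
  std::vector<double> tmp(n);
  for (int c = 0; c < k; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    if (m == 8) {
      pass8(bb.data(), aa.data(), x, tmp.data(), n, &zi[0], +1);
      pass8(bb.data(), aa.data(), tmp.data(), y, n, &zi[0], -1);
    } else {
      pass_gen(bb.data(), aa.data(), m, x, tmp.data(), n, &zi[0], +1);
      pass_gen(bb.data(), aa.data(), m, tmp.data(), y, n, &zi[0], -1);
    }
  }
  return Y;
}

// Linear-phase FIR convolution of each column, delay-compensated by
// (nh-1)/2 samples, zero-padded edges, evaluated only at output positions
// 1, 1+stride, ... (polyphase decimation when stride > 1).
// [[Rcpp::export(name = ".fir_filter_cols")]]
NumericMatrix fir_filter_cols(NumericVector h, NumericMatrix X,
                              int stride = 1) {
  int nh = h.size(), n = X.nrow(), k = X.ncol();
  int d = (nh - 1) / 2;
  int nout = (n + stride - 1) / stride;
  NumericMatrix Y(nout, k);
  for (int c = 0; c < k; ++c) {
    const double* __restrict__ x = &X(0, c);
    double* __restrict__ y = &Y(0, c);
    for (int o = 0; o < nout; ++o) {
      int t = o * stride + d;
      double acc = 0.0;
      int jlo = std::max(0, t - n + 1), jhi = std::min(nh - 1, t);
      for (int j = jlo; j <= jhi; ++j) acc += h[j] * x[t - j];
      y[o] = acc;
    }
  }
  return Y;
}
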