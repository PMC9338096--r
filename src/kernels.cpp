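// Hot kernels of the 1D network engine: im2col gather / col2im scatter
// for convolutions and max-pooling forward/backward. Activations are
// (rows = batch*length, cols = channels) matrices; window indices are
// 1-based with values outside [1, nrow] meaning zero padding.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int n = x.nrow(), cin = x.ncol();
  const int M = idx.nrow(), k = idx.ncol();
  NumericMatrix out(M, k * cin);
  for (int j = 0; j < k; ++j) {
    const int* id = &idx(0, j);
    for (int c = 0; c < cin; ++c) {
      const double* xc = &x(0, c);
      double* oc = &out(0, j * cin + c);
      for (int r = 0; r < M; ++r) {
        const int p = id[r];
        oc[r] = (p >= 1 && p <= n) ? xc[p - 1] : 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dxc, const IntegerMatrix& idx,
                         const int n) {
  const int M = idx.nrow(), k = idx.ncol();
  const int cin = dxc.ncol() / k;
  NumericMatrix dx(n, cin);
  for (int j = 0; j < k; ++j) {
    const int* id = &idx(0, j);
    for (int c = 0; c < cin; ++c) {
      const double* gc = &dxc(0, j * cin + c);
      double* oc = &dx(0, c);
      for (int r = 0; r < M; ++r) {
        const int p = id[r];
        if (p >= 1 && p <= n) oc[p - 1] += gc[r];
      }
    }
  }
  return dx;
}

// Non-overlapping max pool (stride == pool, length divisible): returns the
// pooled values and the 1-based within-window argmax (first maximum).
// [[Rcpp::export]]
List cpp_pool_fwd(const NumericMatrix& x, const int p) {
  const int n = x.nrow(), C = x.ncol(), M = n / p;
  NumericMatrix out(M, C);
  IntegerMatrix arg(M, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    int* ac = &arg(0, c);
    for (int m = 0; m < M; ++m) {
      const double* w = xc + (size_t)m * p;
      double best = w[0];
      int bi = 0;
      for (int q = 1; q < p; ++q)
        if (w[q] > best) { best = w[q]; bi = q; }
      oc[m] = best;
      ac[m] = bi + 1;
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dout, const IntegerMatrix& arg,
                           const int p) {
  const int M = dout.nrow(), C = dout.ncol(), n = M * p;
  NumericMatrix dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dout(0, c);
    const int* ac = &arg(0, c);
    double* oc = &dx(0, c);
    for (int m = 0; m < M; ++m)
      oc[(size_t)m * p + (ac[m] - 1)] = gc[m];
  }
  return dx;
}

// Overlapping / padded max pool used by the residual stem: windows given
// by an index matrix (pad entries outside [1, n] are -Inf).
// [[Rcpp::export]]
List cpp_pool_window_fwd(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int n = x.nrow(), C = x.ncol();
  const int M = idx.nrow(), k = idx.ncol();
  NumericMatrix out(M, C);
  IntegerMatrix arg(M, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    int* ac = &arg(0, c);
    for (int r = 0; r < M; ++r) {
      double best = R_NegInf;
      int bi = 1;
      for (int j = 0; j < k; ++j) {
        const int pix = idx(r, j);
        if (pix >= 1 && pix <= n) {
          const double v = xc[pix - 1];
          if (v > best) { best = v; bi = j + 1; }
        }
      }
      oc[r] = best;
      ac[r] = bi;
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_window_bwd(const NumericMatrix& dout,
                                  const IntegerMatrix& arg,
                                  const IntegerMatrix& idx, const int n) {
  const int M = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dout(0, c);
    const int* ac = &arg(0, c);
    double* oc = &dx(0, c);
    for (int r = 0; r < M; ++r) {
      const int pix = idx(r, ac[r] - 1);
      if (pix >= 1 && pix <= n) oc[pix - 1] += gc[r];
    }
  }
  return dx;
}
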