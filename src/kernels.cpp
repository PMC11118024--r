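// Fused numeric kernels for the tape engine. Activations are (S*G) x C
// matrices whose row index runs spatial-fastest (S spatial cells, G
// frame/batch groups, C channels). The depthwise 3x3 convolution and its
// weight gradient are the memory-bound inner loops of every bottleneck
// block, so they are single-pass here instead of 9 shift/multiply/add
// passes in R.

#include <Rcpp.h>
using namespace Rcpp;

// out[base+s, c] = sum_t W(t,c) * x[base+idx(s,t)-1, c]  (+ bias[c])
// idx entries are 1-based spatial sources, 0 meaning "outside the grid".
// [[Rcpp::export]]
NumericMatrix cpp_dwmix(const NumericMatrix& x, const NumericMatrix& W,
                        const IntegerMatrix& idx,
                        Nullable<NumericVector> bias) {
  const int S = idx.nrow(), T = idx.ncol();
  const int N = x.nrow(), C = x.ncol(), G = N / S;
  NumericMatrix out(N, C);
  NumericVector b;
  bool has_b = bias.isNotNull();
  if (has_b) b = bias.get();
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    if (has_b) std::fill(oc, oc + N, b[c]);
    for (int t = 0; t < T; ++t) {
      const double w = W(t, c);
      if (w == 0.0) continue;
      const int* id = &idx(0, t);
      for (int g = 0; g < G; ++g) {
        const int base = g * S;
        for (int s = 0; s < S; ++s) {
          const int src = id[s];
          if (src > 0) oc[base + s] += w * xc[base + src - 1];
        }
      }
    }
  }
  return out;
}

// weight gradient of cpp_dwmix: out(t,c) = sum_{g,s} x[base+idx(s,t)-1, c]
// * grad[base+s, c]
// [[Rcpp::export]]
NumericMatrix cpp_dwwgrad(const NumericMatrix& x, const NumericMatrix& grad,
                          const IntegerMatrix& idx) {
  const int S = idx.nrow(), T = idx.ncol();
  const int N = x.nrow(), C = x.ncol(), G = N / S;
  NumericMatrix out(T, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* gc = &grad(0, c);
    for (int t = 0; t < T; ++t) {
      const int* id = &idx(0, t);
      double acc = 0.0;
      for (int g = 0; g < G; ++g) {
        const int base = g * S;
        for (int s = 0; s < S; ++s) {
          const int src = id[s];
          if (src > 0) acc += xc[base + src - 1] * gc[base + s];
        }
      }
      out(t, c) = acc;
    }
  }
  return out;
}

// out = x * w (w recycled along rows)
// [[Rcpp::export]]
NumericMatrix cpp_scalecols(const NumericMatrix& x, const NumericVector& w) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    const double wc = w[c];
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < N; ++i) oc[i] = xc[i] * wc;
  }
  return out;
}

// out[c] = sum_i x(i,c) * g(i,c)
// [[Rcpp::export]]
NumericMatrix cpp_colsum_prod(const NumericMatrix& x,
                              const NumericMatrix& g) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix out(1, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* gc = &g(0, c);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) acc += xc[i] * gc[i];
    out(0, c) = acc;
  }
  return out;
}

// out = x + b (b recycled along rows)
// [[Rcpp::export]]
NumericMatrix cpp_addbias(const NumericMatrix& x, const NumericVector& b) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < N; ++i) oc[i] = xc[i] + bc;
  }
  return out;
}

// clamp to [0, 6]; also returns the 0/1 interior mask used by the vjp
// [[Rcpp::export]]
List cpp_relu6(const NumericMatrix& x) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix val(N, C), mask(N, C);
  const int n = N * C;
  const double* xi = x.begin();
  double* vi = val.begin();
  double* mi = mask.begin();
  for (int i = 0; i < n; ++i) {
    const double v = xi[i];
    if (v <= 0.0) { vi[i] = 0.0; mi[i] = 0.0; }
    else if (v >= 6.0) { vi[i] = 6.0; mi[i] = 0.0; }
    else { vi[i] = v; mi[i] = 1.0; }
  }
  return List::create(Named("value") = val, Named("mask") = mask);
}
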