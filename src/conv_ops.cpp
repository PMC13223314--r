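// im2col / col2im kernels for the 1-D convolution engine.
// Arrays are column-major with the batch dimension fastest (N x T x C), so a
// (n, t, c) block of contiguous batch entries can be copied as a unit.
// Padding is folded in: source/target time index is t*s + j - pad_l; positions
// outside [0, T) read as zero (gather) or are dropped (scatter), matching the
// "same"-style padding rule of the R layer code.

#include <Rcpp.h>
using namespace Rcpp;

// x: N x T_in x C (dim attr not required; flat layout assumed)
// returns (N*T_out) x (k*C) patch matrix
// [[Rcpp::export]]
NumericMatrix cpp_conv_gather(NumericVector x, int n, int t_in, int c_ch,
                              int k, int s, int t_out, int pad_l) {
  NumericMatrix out(n * t_out, k * c_ch);
  const double* xs = x.begin();
  for (int c = 0; c < c_ch; ++c) {
    const double* xc = xs + (size_t)n * t_in * c;
    for (int j = 0; j < k; ++j) {
      double* col = &out(0, j + c * k);
      for (int t = 0; t < t_out; ++t) {
        int ti = t * s + j - pad_l;
        if (ti < 0 || ti >= t_in) continue; // zero padding
        const double* src = xc + (size_t)n * ti;
        std::copy(src, src + n, col + (size_t)n * t);
      }
    }
  }
  return out;
}

// adjoint: (N*T_out) x (k*C) patches accumulated into N x T_in x C
// [[Rcpp::export]]
NumericVector cpp_conv_scatter(NumericMatrix m, int n, int t_in, int c_ch,
                               int k, int s, int t_out, int pad_l) {
  NumericVector out((R_xlen_t)n * t_in * c_ch);
  double* os = out.begin();
  for (int c = 0; c < c_ch; ++c) {
    double* oc = os + (size_t)n * t_in * c;
    for (int j = 0; j < k; ++j) {
      const double* col = &m(0, j + c * k);
      for (int t = 0; t < t_out; ++t) {
        int ti = t * s + j - pad_l;
        if (ti < 0 || ti >= t_in) continue;
        double* dst = oc + (size_t)n * ti;
        const double* src = col + (size_t)n * t;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, t_in, c_ch);
  return out;
}
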