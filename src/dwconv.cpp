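// Depthwise 1-D convolution kernels (same padding), the hot loops of the
// detector's forward and backward passes. Input xp is already zero-padded
// by (k-1)/2 rows on each side; columns are channels.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix dwconv_fwd_cpp(const NumericMatrix& xp, const NumericMatrix& w,
                             const int n) {
  const int k = w.nrow(), c = w.ncol();
  NumericMatrix y(n, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = &xp(0, ch);
    double* yc = &y(0, ch);
    for (int j = 0; j < k; ++j) {
      const double wj = w(j, ch);
      const double* xs = xc + j;
      for (int t = 0; t < n; ++t) yc[t] += wj * xs[t];
    }
  }
  return y;
}

// gradient wrt weights and (unpadded) input
// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericMatrix& dy, const NumericMatrix& xp,
                    const NumericMatrix& w) {
  const int n = dy.nrow(), c = dy.ncol(), k = w.nrow();
  const int p = (k - 1) / 2;
  NumericMatrix dw(k, c), dx(n, c);
  std::vector<double> dxp(n + 2 * p);
  for (int ch = 0; ch < c; ++ch) {
    std::fill(dxp.begin(), dxp.end(), 0.0);
    const double* dyc = &dy(0, ch);
    const double* xc = &xp(0, ch);
    for (int j = 0; j < k; ++j) {
      const double wj = w(j, ch);
      double s = 0.0;
      double* dst = dxp.data() + j;
      const double* xs = xc + j;
      for (int t = 0; t < n; ++t) {
        dst[t] += wj * dyc[t];
        s += xs[t] * dyc[t];
      }
      dw(j, ch) = s;
    }
    double* dxc = &dx(0, ch);
    for (int t = 0; t < n; ++t) dxc[t] = dxp[t + p];
  }
  return List::create(_["dw"] = dw, _["dx"] = dx);
}
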