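#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied down each column of X.
// b, a: transfer-function coefficients, a[0] == 1 assumed (normalized in R).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericMatrix iir_filter_cpp(NumericVector b, NumericVector a, NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  const int nb = b.size(), na = a.size();
  const int nw = std::max(nb, na);
  NumericMatrix Y(n, m);
  std::vector<double> w(nw, 0.0);
  for (int c = 0; c < m; ++c) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      const double x = X(t, c);
      const double y = b[0] * x + w[0];
      for (int k = 1; k < nw; ++k) {
        const double bk = (k < nb) ? b[k] : 0.0;
        const double ak = (k < na) ? a[k] : 0.0;
        w[k - 1] = bk * x - ak * y + ((k < nw - 1) ? w[k] : 0.0);
      }
      Y(t, c) = y;
    }
  }
  return Y;
}

// Centered FIR filtering (cross-correlation with a centered kernel of odd
// length); edges are zero-padded.
// [[Rcpp::export(name = ".fir_centered_cpp")]]
NumericMatrix fir_centered_cpp(NumericMatrix X, NumericVector kernel) {
  const int n = X.nrow(), m = X.ncol();
  const int len = kernel.size();
  const int h = (len - 1) / 2;
  NumericMatrix Y(n, m);
  std::vector<double> k(kernel.begin(), kernel.end());
  const double* kp = k.data();
  for (int c = 0; c < m; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    const int lo = std::min(h, n);
    const int hi = std::max(lo, n - h);
    for (int t = 0; t < lo; ++t) {           // left edge (zero padding)
      double acc = 0.0;
      for (int j = h - t; j < len && t + j - h < n; ++j) acc += kp[j] * x[t + j - h];
      y[t] = acc;
    }
    for (int t = lo; t < hi; ++t) {          // interior, branch-free
      double acc = 0.0;
      const double* xs = x + t - h;
      for (int j = 0; j < len; ++j) acc += kp[j] * xs[j];
      y[t] = acc;
    }
    for (int t = hi; t < n; ++t) {           // right edge
      double acc = 0.0;
      const int j1 = n - t + h;
      for (int j = 0; j < j1; ++j) acc += kp[j] * x[t + j - h];
      y[t] = acc;
    }
  }
  return Y;
}
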