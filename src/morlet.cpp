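#include <Rcpp.h>
using namespace Rcpp;

// Band-averaged Morlet wavelet power by direct strided convolution.
//
// X:      time x nsignal matrix (each column one trial-channel signal)
// ker_re, ker_im: list of kernel tap vectors (one per 1-Hz frequency bin),
//         each of odd length, centered. The Morlet structure is exploited:
//         the real part must be symmetric and the imaginary part
//         antisymmetric about the center tap (true for a Gaussian envelope
//         times a complex exponential), halving the multiplications.
// stride: output one power sample every `stride` input samples
//
// Returns a (nout x nsignal) matrix of power averaged over the bins; |.|^2
// makes the conjugation implied by convolution vs correlation irrelevant.
// Output samples whose support extends past the signal edge for the widest
// kernel in the band are NA (wavelet edge invalidation).
// [[Rcpp::export(name = ".morlet_band_power_cpp")]]
NumericMatrix morlet_band_power_cpp(NumericMatrix X, List ker_re, List ker_im,
                                    int stride) {
  const int nt = X.nrow();
  const int ns = X.ncol();
  const int nk = ker_re.size();
  const int nout = (nt + stride - 1) / stride;
  NumericMatrix out(nout, ns);

  int max_half = 0;
  std::vector<std::vector<double>> kre(nk), kim(nk);
  std::vector<int> half(nk);
  std::vector<double> k0(nk);
  for (int k = 0; k < nk; ++k) {
    NumericVector re = ker_re[k], im = ker_im[k];
    const int h = (re.size() - 1) / 2;
    half[k] = h;
    if (h > max_half) max_half = h;
    k0[k] = re[h];
    kre[k].resize(h); kim[k].resize(h);
    for (int d = 1; d <= h; ++d) {     // one-sided taps (lag +d)
      kre[k][d - 1] = re[h + d];
      kim[k][d - 1] = im[h + d];
    }
  }

  for (int s = 0; s < ns; ++s) {
    const double* x = &X(0, s);
    for (int o = 0; o < nout; ++o) {
      const int t = o * stride;                  // center sample (0-based)
      if (t < max_half || t >= nt - max_half) {
        out(o, s) = NA_REAL;
        continue;
      }
      double acc = 0.0;
      for (int k = 0; k < nk; ++k) {
        const int h = half[k];
        const double* kr = kre[k].data();
        const double* ki = kim[k].data();
        double sr = k0[k] * x[t];
        double si = 0.0;
        for (int d = 1; d <= h; ++d) {
          const double sum = x[t + d] + x[t - d];
          const double dif = x[t + d] - x[t - d];
          sr += kr[d - 1] * sum;
          si += ki[d - 1] * dif;
        }
        acc += sr * sr + si * si;
      }
      out(o, s) = acc / nk;
    }
  }
  return out;
}
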