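#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. a[0] must be 1 (normalised in R).
// zi holds the initial delay-line state (length max(na, nb) - 1).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int n = x.size();
  int nfilt = std::max(a.size(), b.size());
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  std::vector<double> z(nfilt - 1, 0.0);
  for (int i = 0; i < zi.size() && i < nfilt - 1; ++i) z[i] = zi[i];

  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + z[0];
    for (int i = 0; i < nfilt - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    z[nfilt - 2] = bb[nfilt - 1] * xm - aa[nfilt - 1] * ym;
    y[m] = ym;
  }
  return y;
}

static inline void sos_pass(const double* sos, int nsec, const double* zi,
                            std::vector<double>& x) {
  int n = (int)x.size();
  double x0 = x[0];
  for (int s = 0; s < nsec; ++s) {
    const double b0 = sos[s], b1 = sos[s + nsec], b2 = sos[s + 2 * nsec];
    const double a1 = sos[s + 4 * nsec], a2 = sos[s + 5 * nsec];
    double z0 = zi[2 * s] * x0, z1 = zi[2 * s + 1] * x0;
    for (int m = 0; m < n; ++m) {
      double xm = x[m];
      double ym = b0 * xm + z0;
      z0 = b1 * xm + z1 - a1 * ym;
      z1 = b2 * xm - a2 * ym;
      x[m] = ym;
    }
    x0 = x[0];  // next section's steady state scales to its own input start
  }
}

// Forward-backward filtering through a cascade of second-order sections
// (columns b0 b1 b2 a0 a1 a2, a0 normalised to 1), with odd-reflection
// padding of `padlen` samples and per-section steady-state initial
// conditions `zi` (2 x nsec, unit-step state).
// [[Rcpp::export(name = ".sosfiltfilt_cpp")]]
NumericVector sosfiltfilt_cpp(NumericMatrix sos, NumericVector x,
                              int padlen, NumericMatrix zi) {
  int n = x.size(), nsec = sos.nrow();
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  int ne = n + 2 * padlen;
  std::vector<double> ext(ne);
  for (int i = 0; i < padlen; ++i) ext[i] = 2 * x[0] - x[padlen - i];
  for (int i = 0; i < n; ++i) ext[padlen + i] = x[i];
  for (int i = 0; i < padlen; ++i)
    ext[padlen + n + i] = 2 * x[n - 1] - x[n - 2 - i];

  // column-major layout of sos: sos(s, c) = sos[s + c*nsec]
  std::vector<double> soscol(6 * nsec), zic(2 * nsec);
  for (int c = 0; c < 6; ++c)
    for (int s = 0; s < nsec; ++s) soscol[s + c * nsec] = sos(s, c);
  for (int s = 0; s < nsec; ++s) {
    zic[2 * s] = zi(0, s);
    zic[2 * s + 1] = zi(1, s);
  }

  sos_pass(soscol.data(), nsec, zic.data(), ext);
  std::reverse(ext.begin(), ext.end());
  sos_pass(soscol.data(), nsec, zic.data(), ext);
  std::reverse(ext.begin(), ext.end());

  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = ext[padlen + i];
  return y;
}
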