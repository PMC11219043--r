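#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR pass, zero initial state.
// b, a are padded to length ns + 1 with a[0] == 1.
static void iir_pass(const double* x, double* y, int n,
                     const double* b, const double* a, int ns,
                     double* z) {
  for (int k = 0; k < ns; ++k) z[k] = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < ns - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[ns - 1] = b[ns] * xi - a[ns] * yi;
    y[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filter with reflective end padding.
// b, a: transfer-function coefficients with a[0] == 1.
// [[Rcpp::export(name = ".zerophase_iir")]]
NumericVector zerophase_iir(NumericVector xv, NumericVector bv,
                            NumericVector av, int npad) {
  const int n = xv.size();
  if (npad > n - 1) npad = n - 1;
  if (npad < 0) npad = 0;
  const int ns = std::max(bv.size(), av.size()) - 1;
  std::vector<double> b(ns + 1, 0.0), a(ns + 1, 0.0), z(ns);
  for (int k = 0; k < bv.size(); ++k) b[k] = bv[k];
  for (int k = 0; k < av.size(); ++k) a[k] = av[k];
  const double* x = REAL(xv);
  const int m = n + 2 * npad;
  std::vector<double> xp(m), y1(m);
  // odd reflection about the end samples keeps the signal value-continuous
  for (int i = 0; i < npad; ++i) xp[i] = 2.0 * x[0] - x[npad - i];
  std::copy(x, x + n, xp.begin() + npad);
  for (int i = 0; i < npad; ++i) xp[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iir_pass(xp.data(), y1.data(), m, b.data(), a.data(), ns, z.data());
  std::reverse(y1.begin(), y1.end());
  iir_pass(y1.data(), xp.data(), m, b.data(), a.data(), ns, z.data());
  NumericVector outv(n);
  double* out = REAL(outv);
  // xp now holds the backward pass in reversed order
  for (int i = 0; i < n; ++i) out[i] = xp[m - 1 - (npad + i)];
  return outv;
}

// Centered FIR convolution with an odd-length kernel h; the first and last
// (length(h)-1)/2 output samples are left as NA for the caller to fill
// (polynomial-extrapolated endpoint rows of the Savitzky-Golay design).
// [[Rcpp::export(name = ".fir_center")]]
NumericVector fir_center(NumericVector xv, NumericVector hv) {
  const int n = xv.size(), k = hv.size(), half = (k - 1) / 2;
  const double* x = REAL(xv);
  const double* h = REAL(hv);
  NumericVector outv(n, NA_REAL);
  double* out = REAL(outv);
  if (n < k) return outv;
  for (int i = half; i < n - half; ++i) {
    double acc = 0.0;
    const double* xi = x + i - half;
    for (int j = 0; j < k; ++j) acc += h[j] * xi[j];
    out[i] = acc;
  }
  return outv;
}
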