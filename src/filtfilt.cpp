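#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase IIR filtering of matrix columns: forward-backward direct-form-II
// transposed filtering with odd-reflection edge padding. Initial conditions
// use the steady-state identity: filtering from state zi * x[0] equals
// filtering (x - x[0]) from zero state plus x[0] * H(1).
// [[Rcpp::export]]
NumericMatrix filtfilt_cpp(NumericVector b, NumericVector a, NumericMatrix x) {
  const int nb = b.size(), na = a.size();
  const int ord = std::max(nb, na) - 1;
  const int n = x.nrow(), nc = x.ncol();
  const int npad = 3 * ord;
  if (n <= npad) stop("signal too short for the filter's edge padding");
  const double a0 = a[0];
  std::vector<double> bb(ord + 1, 0.0), aa(ord + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  double sb = 0.0, sa = 0.0;
  for (int i = 0; i <= ord; ++i) { sb += bb[i]; sa += aa[i]; }
  const double H1 = sb / sa;

  const int m = n + 2 * npad;
  NumericMatrix out(n, nc);
  std::vector<double> w(m), z(ord);

  for (int c = 0; c < nc; ++c) {
    const double* xc = &x(0, c);
    // odd reflection padding
    for (int i = 0; i < npad; ++i) w[i] = 2.0 * xc[0] - xc[npad - i];
    for (int i = 0; i < n; ++i) w[npad + i] = xc[i];
    for (int i = 0; i < npad; ++i) w[npad + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];

    for (int pass = 0; pass < 2; ++pass) {
      const double x0 = (pass == 0) ? w[0] : w[m - 1];
      std::fill(z.begin(), z.end(), 0.0);
      if (pass == 0) {
        for (int i = 0; i < m; ++i) {
          const double xi = w[i] - x0;
          const double yi = bb[0] * xi + z[0];
          for (int k = 0; k < ord - 1; ++k)
            z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
          z[ord - 1] = bb[ord] * xi - aa[ord] * yi;
          w[i] = yi + x0 * H1;
        }
      } else {
        for (int i = m - 1; i >= 0; --i) {
          const double xi = w[i] - x0;
          const double yi = bb[0] * xi + z[0];
          for (int k = 0; k < ord - 1; ++k)
            z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
          z[ord - 1] = bb[ord] * xi - aa[ord] * yi;
          w[i] = yi + x0 * H1;
        }
      }
    }
    for (int i = 0; i < n; ++i) out(i, c) = w[npad + i];
  }
  return out;
}
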