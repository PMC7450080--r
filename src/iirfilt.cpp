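#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// direct-form II transposed IIR filter, a[0] assumed 1 (normalized upstream)
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 std::vector<double>& x) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 1; j <= nz; ++j) {
      double bj = j < nb ? b[j] : 0.0;
      double aj = j < na ? a[j] : 0.0;
      double znext = (j < nz) ? z[j] : 0.0;
      z[j - 1] = bj * xi + znext - aj * yi;
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of each matrix row, with
// odd-reflection edge padding of length 3 * (filter order), as in the
// classical filtfilt scheme.
// [[Rcpp::export(name = ".filtfilt_rows")]]
NumericMatrix filtfilt_rows(NumericVector bv, NumericVector av,
                            NumericMatrix X) {
  std::vector<double> b(bv.begin(), bv.end()), a(av.begin(), av.end());
  if (a[0] != 1.0) {
    double a0 = a[0];
    for (auto& v : b) v /= a0;
    for (auto& v : a) v /= a0;
  }
  int n = X.ncol(), nr = X.nrow();
  int pad = 3 * (std::max(b.size(), a.size()) - 1);
  if (pad >= n) stop("signal too short for filtfilt padding");
  NumericMatrix out(nr, n);
  std::vector<double> w(n + 2 * pad);
  for (int r = 0; r < nr; ++r) {
    for (int i = 0; i < pad; ++i)
      w[i] = 2.0 * X(r, 0) - X(r, pad - i);
    for (int i = 0; i < n; ++i) w[pad + i] = X(r, i);
    for (int i = 0; i < pad; ++i)
      w[pad + n + i] = 2.0 * X(r, n - 1) - X(r, n - 2 - i);
    df2t(b, a, w);
    std::reverse(w.begin(), w.end());
    df2t(b, a, w);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < n; ++i) out(r, i) = w[pad + i];
  }
  return out;
}
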