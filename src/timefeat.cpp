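#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

int lz76_count(IntegerVector s);  // lz76.cpp

// The sixteen time-domain descriptors of one channel; definitions mirror
// the documented feature registry (n-denominator moments, non-excess
// kurtosis, natural-log entropies, LZ76 on the mean-binarized signal).
// [[Rcpp::export(name = ".time_features_cpp")]]
NumericVector time_features_cpp(NumericVector xv, double fs) {
  int n = xv.size();
  const double* x = xv.begin();
  double sx = 0;
  for (int i = 0; i < n; ++i) sx += x[i];
  double mu = sx / n;

  double v = 0, m3 = 0, m4 = 0, energy = 0, sixth = 0;
  double mn = x[0], mx = x[0];
  for (int i = 0; i < n; ++i) {
    double c = x[i] - mu, c2 = c * c;
    v += c2; m3 += c2 * c; m4 += c2 * c2;
    double x2 = x[i] * x[i];
    energy += x2; sixth += x2 * x2 * x2;
    if (x[i] < mn) mn = x[i];
    if (x[i] > mx) mx = x[i];
  }
  v /= n; m3 /= n; m4 /= n;
  double s = std::sqrt(v);
  double skew = v > 0 ? m3 / (s * s * s) : 0;
  double kurt = v > 0 ? m4 / (v * v) : 0;

  // first and second differences
  double sdx = 0, curve = 0;
  for (int i = 1; i < n; ++i) { double d = x[i] - x[i - 1];
    sdx += d; curve += std::fabs(d); }
  double mdx = sdx / (n - 1), vd = 0;
  for (int i = 1; i < n; ++i) { double d = x[i] - x[i - 1] - mdx; vd += d * d; }
  vd /= (n - 1);
  double sddx = 0;
  for (int i = 2; i < n; ++i) sddx += x[i] - 2 * x[i - 1] + x[i - 2];
  double mddx = sddx / (n - 2), vdd = 0;
  for (int i = 2; i < n; ++i) {
    double d = x[i] - 2 * x[i - 1] + x[i - 2] - mddx; vdd += d * d; }
  vdd /= (n - 2);
  double mobility = v > 0 ? std::sqrt(vd / v) : 0;
  double mob_d = vd > 0 ? std::sqrt(vdd / vd) : 0;
  double complexity = mobility > 0 ? mob_d / mobility : 0;

  // Teager energy
  double teager = 0;
  for (int i = 1; i < n - 1; ++i)
    teager += x[i] * x[i] - x[i - 1] * x[i + 1];

  // amplitude-histogram entropy of the z-scored signal on [-5, 5]
  double entropy = 0;
  if (s > 0) {
    std::vector<int> cnt(100, 0);
    for (int i = 0; i < n; ++i) {
      int b = (int)std::ceil(((x[i] - mu) / s + 5.0) / 0.1);
      if (b < 1) b = 1;
      if (b > 100) b = 100;
      cnt[b - 1]++;
    }
    for (int b = 0; b < 100; ++b)
      if (cnt[b] > 0) {
        double p = (double)cnt[b] / n;
        entropy -= p * std::log(p);
      }
  }

  // LZ76 of mean-binarized signal
  IntegerVector bin(n);
  for (int i = 0; i < n; ++i) bin[i] = x[i] >= mu ? 1 : 0;
  double lzc = lz76_count(bin);

  // median (R convention: mean of the two middle order statistics)
  std::vector<double> w(x, x + n);
  double med;
  int h = n / 2;
  std::nth_element(w.begin(), w.begin() + h, w.end());
  if (n % 2 == 1) med = w[h];
  else {
    double hi = w[h];
    med = (*std::max_element(w.begin(), w.begin() + h) + hi) / 2.0;
  }

  NumericVector out = NumericVector::create(
    _["signal_entropy"] = entropy, _["lzc"] = lzc,
    _["curve_length"] = curve, _["energy"] = energy,
    _["nonlinear_energy"] = teager, _["sixth_power"] = sixth,
    _["min"] = mn, _["max"] = mx, _["median"] = med,
    _["variance"] = v, _["std"] = s, _["skew"] = skew,
    _["kurtosis"] = kurt, _["integral"] = sx / fs,
    _["mobility"] = mobility, _["complexity"] = complexity);
  return out;
}
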