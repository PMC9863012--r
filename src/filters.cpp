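#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 (normalized design).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns, 0.0), bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < ns - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (ns > 0) z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
    y[i] = yi;
  }
  return y;
}

// Forward-backward pass: filter, then filter the reversed output and
// reverse again, all in C++ to avoid intermediate copies.
// [[Rcpp::export(name = ".iir_filtfilt_core")]]
NumericVector iir_filtfilt_core(NumericVector b, NumericVector a,
                                NumericVector x) {
  NumericVector y = iir_filter(b, a, x);
  std::reverse(y.begin(), y.end());
  NumericVector y2 = iir_filter(b, a, y);
  std::reverse(y2.begin(), y2.end());
  return y2;
}

// Upward threshold crossings per epoch: a crossing is counted at sample
// i (0-based, i >= 1) when x[i-1] < tau && x[i] >= tau, attributed to the
// epoch holding sample i after skipping `offset` samples; `n_ep` whole
// epochs of `per_epoch` samples are counted, the trailing partial dropped.
// [[Rcpp::export(name = ".count_crossings")]]
IntegerVector count_crossings(NumericVector x, double tau, int offset,
                              int per_epoch, int n_ep) {
  IntegerVector counts(n_ep);
  const int n = x.size();
  const int last = std::min(n, offset + n_ep * per_epoch);
  for (int i = std::max(1, offset); i < last; ++i) {
    if (x[i - 1] < tau && x[i] >= tau) {
      const int ep = (i - offset) / per_epoch;
      if (ep >= 0 && ep < n_ep) counts[ep] += 1;
    }
  }
  return counts;
}

static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

// xoshiro256++ seeded via splitmix64; Box-Muller transform to normals.
// Used for the bulk per-sample noise draws of the synthetic generator,
// where R's rnorm would dominate the simulation cost; the stream is fully
// determined by the (R-drawn) seed.
// [[Rcpp::export(name = ".fast_rnorm")]]
NumericVector fast_rnorm(int n, double seed) {
  uint64_t s[4];
  uint64_t x = (uint64_t)seed;
  for (int i = 0; i < 4; ++i) {        // splitmix64 expansion
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    s[i] = z ^ (z >> 31);
  }
  NumericVector out(n);
  const double TWO_PI = 6.283185307179586476925286766559;
  int i = 0;
  while (i < n) {
    uint64_t r1 = rotl64(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    uint64_t r2 = rotl64(s[0] + s[3], 23) + s[0];
    t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    double u1 = ((double)(r1 >> 11) + 0.5) / 9007199254740992.0;
    double u2 = ((double)(r2 >> 11) + 0.5) / 9007199254740992.0;
    double rad = std::sqrt(-2.0 * std::log(u1));
    out[i] = rad * std::cos(TWO_PI * u2);
    if (i + 1 < n) out[i + 1] = rad * std::sin(TWO_PI * u2);
    i += 2;
  }
  return out;
}
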