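#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Circular binary segmentation, simplified after Olshen et al.:
// on each interval, find the circular arc [i+1..j] maximizing the two-sample
// mean-shift statistic against its complement, assess it with a permutation
// test, accept the split when the permutation p-value <= alpha, recurse.
//
// The observed maximum is an exact scan over all (i, j).  Permuted maxima are
// scanned over all short arcs plus a strided arc-length grid (a hybrid scan in
// the spirit of mature CBS implementations), with sequential early stopping:
// reject the split as soon as the exceedance count passes floor(alpha*B);
// accept it early when no exceedance has occurred after 100 permutations.
//
// RNG: splitmix64 -> xorshift-free deterministic generator, independent of R's
// RNG state so results depend only on the seed argument.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, k)
  uint64_t bounded(uint64_t k) { return next() % k; }
};

struct ScanResult {
  double zmax;
  int i, j;  // arc is [i, j) in 0-based offsets within the interval
};

// Exact max over all arcs [i, i+k), min_width <= k <= m - min_width.
// For fixed k the statistic is monotone in |A*c1 - c2| with A the arc sum,
// so only the max and min sliding-window sums matter.
ScanResult scan_full(const double *S, int m, double T, double sigma,
                     int min_width) {
  // pass 1: branch-free value-only scan (vectorizable) to find the best arc
  // length; pass 2: rescan that single length for the arc position.  Ties
  // break toward the smallest arc length, then the smallest start.
  double zbest = 0.0;
  int kbest = -1;
  for (int k = min_width; k <= m - min_width; ++k) {
    double mx = -1e300, mn = 1e300;
    const double *hi = S + k;
    for (int i = 0; i + k <= m; ++i) {
      double A = hi[i] - S[i];
      mx = A > mx ? A : mx;
      mn = A < mn ? A : mn;
    }
    double c1 = 1.0 / k + 1.0 / (m - k);
    double c2 = T / (m - k);
    double inv_den = 1.0 / (sigma * std::sqrt(c1));
    double zhi = std::fabs(mx * c1 - c2) * inv_den;
    double zlo = std::fabs(mn * c1 - c2) * inv_den;
    double z = zhi > zlo ? zhi : zlo;
    if (z > zbest) { zbest = z; kbest = k; }
  }
  if (kbest < 0) return ScanResult{0.0, -1, -1};
  int k = kbest;
  double c1 = 1.0 / k + 1.0 / (m - k);
  double c2 = T / (m - k);
  double inv_den = 1.0 / (sigma * std::sqrt(c1));
  for (int i = 0; i + k <= m; ++i) {
    double z = std::fabs((S[i + k] - S[i]) * c1 - c2) * inv_den;
    if (z >= zbest) return ScanResult{z, i, i + k};
  }
  return ScanResult{0.0, -1, -1};  // unreachable
}

// Approximate max for permuted data: all short arcs (k <= short_cap or
// k >= m - short_cap) plus a strided grid of arc lengths.
double scan_proxy(const double *S, int m, double T, double sigma,
                  int min_width, int short_cap, int grid_pts) {
  double zmax = 0.0;
  auto do_k = [&](int k) {
    if (k < min_width || k > m - min_width) return;
    double mx = -1e300, mn = 1e300;
    const double *hi = S + k;
    for (int i = 0; i + k <= m; ++i) {
      double A = hi[i] - S[i];
      mx = A > mx ? A : mx;
      mn = A < mn ? A : mn;
    }
    double c1 = 1.0 / k + 1.0 / (m - k);
    double c2 = T / (m - k);
    double inv_den = 1.0 / (sigma * std::sqrt(c1));
    double z = std::max(std::fabs(mx * c1 - c2), std::fabs(mn * c1 - c2)) *
               inv_den;
    if (z > zmax) zmax = z;
  };
  int hi_short = std::min(short_cap, m - min_width);
  for (int k = min_width; k <= hi_short; ++k) do_k(k);
  for (int k = std::max(min_width, m - short_cap); k <= m - min_width; ++k)
    do_k(k);
  if (grid_pts > 0) {
    double step = (double)m / (grid_pts + 1);
    for (int q = 1; q <= grid_pts; ++q) {
      int k = (int)std::floor(q * step);
      if (k > short_cap && k < m - short_cap) do_k(k);
    }
  }
  return zmax;
}

}  // namespace

// [[Rcpp::export(name = ".cbs_changepoints")]]
IntegerVector cbs_changepoints(NumericVector x, double alpha, int nperm,
                               int min_width, double seed, int short_cap,
                               int grid_pts) {
  const int n = x.size();
  if (n < 2) return IntegerVector(0);
  std::vector<int> bks;  // 0-based changepoints: segment boundary before index
  std::vector<std::pair<int, int> > stack;  // [lo, hi)
  stack.push_back(std::make_pair(0, n));
  uint64_t interval_counter = 0;
  const int exceed_cap = (int)std::floor(alpha * nperm);

  std::vector<double> v, S;
  while (!stack.empty()) {
    int lo = stack.back().first, hi = stack.back().second;
    stack.pop_back();
    int m = hi - lo;
    if (m < 2 * min_width) continue;
    ++interval_counter;

    v.assign(x.begin() + lo, x.begin() + hi);
    S.assign(m + 1, 0.0);
    double sumsq = 0.0;
    for (int i = 0; i < m; ++i) {
      S[i + 1] = S[i] + v[i];
      sumsq += v[i] * v[i];
    }
    double T = S[m];
    double mu = T / m;
    double var = sumsq / m - mu * mu;
    if (var <= 1e-20) continue;  // flat interval
    double sigma = std::sqrt(var);

    ScanResult obs = scan_full(S.data(), m, T, sigma, min_width);
    if (obs.i < 0 || obs.zmax <= 0) continue;

    Rng rng((uint64_t)seed * 1315423911ULL + interval_counter);
    int exceed = 0, done = 0;
    bool rejected = false;
    std::vector<double> pv(v), pS(m + 1, 0.0);
    for (int b = 1; b <= nperm; ++b) {
      // Fisher-Yates shuffle
      for (int i = m - 1; i > 0; --i) {
        int jj = (int)rng.bounded((uint64_t)(i + 1));
        std::swap(pv[i], pv[jj]);
      }
      for (int i = 0; i < m; ++i) pS[i + 1] = pS[i] + pv[i];
      double pz = scan_proxy(pS.data(), m, T, sigma, min_width, short_cap,
                             grid_pts);
      if (pz >= obs.zmax - 1e-12) ++exceed;
      done = b;
      if (exceed > exceed_cap) { rejected = true; break; }
      if (b == 100 && exceed == 0) break;  // early acceptance
    }
    (void)done;
    if (rejected || exceed > exceed_cap) continue;

    // accepted: changepoints at lo + obs.i and lo + obs.j
    int a = lo + obs.i, bnd = lo + obs.j;
    if (a > lo) bks.push_back(a);
    if (bnd < hi) bks.push_back(bnd);
    if (a - lo >= 2 * min_width) stack.push_back(std::make_pair(lo, a));
    if (bnd - a >= 2 * min_width) stack.push_back(std::make_pair(a, bnd));
    if (hi - bnd >= 2 * min_width) stack.push_back(std::make_pair(bnd, hi));
  }
  std::sort(bks.begin(), bks.end());
  bks.erase(std::unique(bks.begin(), bks.end()), bks.end());
  return wrap(bks);  // 0-based boundaries; R side converts
}
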