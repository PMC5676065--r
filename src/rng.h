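#ifndef MITOSIM_RNG_H
#define MITOSIM_RNG_H

#include <cstdint>
#include <cmath>

// Counter-seeded xoshiro256** stream with splitmix64 initialisation.
// Each cell agent owns one stream derived from (master seed, cell index),
// so trajectories are independent of the order in which cells are stepped.

namespace mitosim {

inline std::uint64_t splitmix64(std::uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class RNG {
 public:
  explicit RNG(std::uint64_t seed) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  std::uint64_t next_u64() {
    const std::uint64_t result = rotl(s[1] * 5ULL, 7) * 9ULL;
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  double runif() {
    return (next_u64() >> 11) * 0x1.0p-53;
  }

  double runif(double lo, double hi) { return lo + (hi - lo) * runif(); }

  // standard normal, Box-Muller with cache
  double rnorm() {
    if (have_cache) { have_cache = false; return cache; }
    double u1 = runif(), u2 = runif();
    while (u1 <= 0.0) u1 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    cache = r * std::sin(th);
    have_cache = true;
    return r * std::cos(th);
  }

  // Poisson: Knuth product method for small mean, normal approximation for
  // large mean (the simulator's event rates keep lambda well below the
  // switch point in practice).
  int rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= runif(); } while (p > L);
      return k - 1;
    }
    double x = std::floor(lambda + std::sqrt(lambda) * rnorm() + 0.5);
    return x < 0.0 ? 0 : static_cast<int>(x);
  }

  // Binomial by CDF inversion (sizes here are small mtDNA pools).
  int rbinom(int n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    double q = 1.0 - p;
    double pmf = std::pow(q, n);   // P(X = 0)
    double cdf = pmf;
    double u = runif();
    int k = 0;
    while (u > cdf && k < n) {
      ++k;
      pmf *= (static_cast<double>(n - k + 1) / k) * (p / q);
      cdf += pmf;
    }
    return k;
  }

  // Triangular(a, c, b) by inverse CDF; supports degenerate limbs.
  double rtri(double a, double c, double b) {
    if (b <= a) return a;
    double u = runif();
    double fc = (c - a) / (b - a);
    if (u < fc)
      return a + std::sqrt(u * (b - a) * (c - a));
    return b - std::sqrt((1.0 - u) * (b - a) * (b - c));
  }

  bool rbernoulli(double p) { return runif() < p; }

 private:
  static std::uint64_t rotl(const std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t s[4];
  double cache = 0.0;
  bool have_cache = false;
};

// Derive the per-cell stream seed for cell `index` (index 0 is the engine's
// own bookkeeping stream).
inline std::uint64_t stream_seed(std::uint64_t master, int index) {
  std::uint64_t x = master ^ 0xA5A5A5A55A5A5A5AULL;
  std::uint64_t s = 0;
  for (int i = 0; i <= index; ++i) s = splitmix64(x);
  return s;
}

}  // namespace mitosim

#endif
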