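#ifndef BVRSIM_RNG_H
#define BVRSIM_RNG_H

#include <cstdint>
#include <random>
#include <cmath>

// SplitMix64: expands a master seed into well-separated per-target seeds so
// that toggling one target's stochasticity does not perturb the draw streams
// of the others.
inline std::uint64_t splitmix64(std::uint64_t &state) {
  std::uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RngEngine {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm_d{0.0, 1.0};

  explicit RngEngine(std::uint64_t seed) {
    std::uint64_t s = seed;
    std::seed_seq seq{splitmix64(s), splitmix64(s), splitmix64(s), splitmix64(s)};
    gen.seed(seq);
  }

  double norm() { return norm_d(gen); }
  double unif() {
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Binomial draw: exact Bernoulli counting for small n, waiting-time
  // (geometric) sampling for small means, Gaussian approximation with
  // continuity correction for large means.
  long binom(long n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    if (p > 0.5) return n - binom(n, 1.0 - p);
    double np = n * p;
    if (n <= 16) {
      long k = 0;
      for (long i = 0; i < n; ++i) if (unif() < p) ++k;
      return k;
    }
    if (np < 10.0) {
      // count geometric inter-arrival gaps fitting in n trials
      double l1p = std::log1p(-p);
      long k = 0;
      double consumed = 0.0;
      while (true) {
        consumed += std::floor(std::log(1.0 - unif()) / l1p) + 1.0;
        if (consumed > (double)n) break;
        ++k;
      }
      return k;
    }
    double sd = std::sqrt(np * (1.0 - p));
    double x = std::floor(np + sd * norm() + 0.5);
    if (x < 0.0) x = 0.0;
    if (x > (double)n) x = (double)n;
    return (long)x;
  }
  // Poisson count; Gaussian approximation for very large rates where the
  // relative error of the approximation is < 1e-2/sqrt(lambda).
  double pois(double lambda) {
    if (lambda <= 0.0) return 0.0;
    if (lambda > 1e5) {
      double x = lambda + std::sqrt(lambda) * norm();
      return x > 0.0 ? x : 0.0;
    }
    return (double)std::poisson_distribution<long>(lambda)(gen);
  }
};

#endif
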