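#ifndef BNMTUNE_RNG_H
#define BNMTUNE_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained xoshiro256++ generator with splitmix64 seeding and a
// polar Box-Muller normal variate. Keeps simulations bitwise reproducible
// for a given integer seed, independent of R's global RNG state.
namespace bnm {

struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double rnorm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, r2;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// derive a stream seed for sub-simulations (per-trial, per-stage)
inline uint64_t mix_seed(uint64_t seed, uint64_t stream) {
  uint64_t x = seed ^ (0x9e3779b97f4a7c15ULL * (stream + 1));
  return Rng::splitmix64(x);
}

// firing-rate transfer function r(I) = (aI - b) / (1 - exp(-d (aI - b)))
// with the removable singularity at aI = b handled by series expansion.
inline double transfer(double I, double a, double b, double d) {
  const double x = a * I - b;
  const double dx = d * x;
  if (std::fabs(dx) < 1e-10) {
    // x/(1 - exp(-dx)) = 1/d + x/2 + d x^2/12 + O(x^4)
    return 1.0 / d + x / 2.0 + d * x * x / 12.0;
  }
  // expm1 avoids cancellation in 1 - exp(-dx) for small dx
  return x / (-std::expm1(-dx));
}

} // namespace bnm

#endif
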