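#pragma once
#include <cstdint>
#include <cmath>

// Self-contained xoshiro256+ stream seeded through splitmix64, with a
// Marsaglia-polar Gaussian. Keeps long runs deterministic from a single
// integer seed and independent of the R RNG state.
struct Xoshiro {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Xoshiro(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  inline double norm() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};
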