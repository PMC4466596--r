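#ifndef RULEFLEX_RNG_H
#define RULEFLEX_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded generator (xoshiro256++ seeded via
// splitmix64) so that trajectories are reproducible bit-for-bit across
// platforms independently of R's RNG state.
struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
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

  // uniform in (0,1)
  inline double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  bool have_spare;
  double spare;

  // standard normal via Box-Muller (polar form avoided to keep the
  // consumption of uniforms deterministic per draw pair)
  inline double rnorm() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u1 = runif();
    double u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

#endif
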