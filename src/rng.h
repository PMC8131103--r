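#ifndef ADHESIM_RNG_H
#define ADHESIM_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained xoshiro256++ generator so that simulation trajectories are
// bit-reproducible from a single integer seed, independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in [0, n)
  int unif_int(int n) { return (int)(unif() * n) % n; }

  // Binomial(n, q) draws by geometric skipping; efficient when n*q is small
  // (q is always <= 0.5 where this is used). Exact for all q in [0, 1).
  int binom_skip(int n, double q) {
    if (q <= 0.0 || n <= 0) return 0;
    if (q >= 1.0) return n;
    const double lq = std::log1p(-q);
    int count = 0;
    double j = -1.0;
    for (;;) {
      j += std::floor(std::log(1.0 - unif()) / lq) + 1.0;
      if (j >= n) break;
      ++count;
    }
    return count;
  }
};

#endif
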