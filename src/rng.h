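#ifndef SUBDRIVER_RNG_H
#define SUBDRIVER_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding; one independent stream per
// (seed, attempt) pair so replicate runs are reproducible regardless of
// execution order.
struct Xoshiro256 {
  uint64_t s[4];

  static inline uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  // independent stream for run `idx` under master `seed`
  static Xoshiro256 stream(uint64_t seed, uint64_t idx) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL * (idx + 1);
    uint64_t h = splitmix64(x);
    x ^= h;
    (void)splitmix64(x);
    return Xoshiro256(x);
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
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

  // uniform on (0, 1): never exactly 0 so -log(unif) is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }

  inline double rexp() { return -std::log(unif()); }
};

#endif
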