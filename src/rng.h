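#pragma once
#include <cstdint>
#include <cmath>

// Self-contained xoshiro256++ generator so that per-trial streams can be
// seeded independently of R's global RNG (deterministic common-random-number
// pairing across paired protocol runs).
struct Xoshiro {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform on (0, 1), never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double expo() { return -std::log(unif()); }

  // Box-Muller (exact) — used where tail accuracy matters
  inline double norm_exact() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }

  inline double norm() { return norm_exact(); }

  // Marsaglia-Tsang ziggurat for standard normals (fast path for the
  // diffusion kernel; exact distribution, rare slow path in the tails)
  struct Zig {
    uint32_t kn[128];
    double wn[128], fn[128];
    Zig() {
      double m1 = 2147483648.0;
      double dn = 3.442619855899, tn = dn;
      const double vn = 9.91256303526217e-3;
      double q = vn / std::exp(-0.5 * dn * dn);
      kn[0] = (uint32_t)((dn / q) * m1);
      kn[1] = 0;
      wn[0] = q / m1;
      wn[127] = dn / m1;
      fn[0] = 1.0;
      fn[127] = std::exp(-0.5 * dn * dn);
      for (int i = 126; i >= 1; i--) {
        dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
        kn[i + 1] = (uint32_t)((dn / tn) * m1);
        tn = dn;
        fn[i] = std::exp(-0.5 * dn * dn);
        wn[i] = dn / m1;
      }
    }
  };
  static const Zig& zig() {
    static Zig z;
    return z;
  }

  inline double norm_fast() {
    const Zig& z = zig();
    for (;;) {
      int32_t hz = (int32_t)(next() >> 32);
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < z.kn[iz]) return hz * z.wn[iz];
      // slow path
      const double r = 3.442619855899;
      double x, y;
      if (iz == 0) {
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      x = hz * z.wn[iz];
      if (z.fn[iz] + unif() * (z.fn[iz - 1] - z.fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
    }
  }

  inline int poisson(double lam) {
    if (lam <= 0.0) return 0;
    if (lam < 30.0) {
      double L = std::exp(-lam), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    double x = std::floor(lam + std::sqrt(lam) * norm() + 0.5);
    return x < 0.0 ? 0 : static_cast<int>(x);
  }
};
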