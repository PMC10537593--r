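#ifndef ZIGZAGRBC_SIMRNG_H
#define ZIGZAGRBC_SIMRNG_H

#include <cstdint>
#include <cmath>

// Small self-contained RNG (mt19937_64 + Box-Muller) so that rendered pixel
// noise is bit-reproducible for a given integer seed, independently of the R
// RNG stream state.
class SimRng {
public:
  explicit SimRng(uint64_t seed) : have_spare_(false) {
    mt_[0] = seed;
    for (int i = 1; i < 312; ++i)
      mt_[i] = 6364136223846793005ULL * (mt_[i - 1] ^ (mt_[i - 1] >> 62)) + i;
    idx_ = 312;
  }

  uint64_t next_u64() {
    if (idx_ >= 312) twist();
    uint64_t x = mt_[idx_++];
    x ^= (x >> 29) & 0x5555555555555555ULL;
    x ^= (x << 17) & 0x71D67FFFEDA60000ULL;
    x ^= (x << 37) & 0xFFF7EEE000000000ULL;
    x ^= (x >> 43);
    return x;
  }

  // uniform in [0, 1)
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }

  // standard normal via the Marsaglia-Tsang ziggurat (128 layers); falls
  // back to the exact tail/edge sampler on the rare rejection path
  double norm() {
    tables();
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next_u64();
      int iz = hz & 127;
      if ((uint32_t)(hz < 0 ? -hz : hz) < kn_[iz]) return hz * wn_[iz];
      if (iz == 0) {  // base strip: exact exponential tail beyond R
        double x, y;
        do {
          double u1 = unif(), u2 = unif();
          if (u1 <= 0.0) u1 = 5e-324;
          x = -std::log(u1) * (1.0 / 3.442619855899);
          y = -std::log(u2 <= 0.0 ? 5e-324 : u2);
        } while (y + y < x * x);
        return hz > 0 ? 3.442619855899 + x : -3.442619855899 - x;
      }
      double x = hz * wn_[iz];
      if (fn_[iz] + unif() * (fn_[iz - 1] - fn_[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }

private:
  void twist() {
    static const uint64_t LM = 0x7FFFFFFFULL, UM = 0xFFFFFFFF80000000ULL;
    for (int i = 0; i < 312; ++i) {
      uint64_t x = (mt_[i] & UM) + (mt_[(i + 1) % 312] & LM);
      uint64_t xA = x >> 1;
      if (x & 1ULL) xA ^= 0xB5026F5AA96619E9ULL;
      mt_[i] = mt_[(i + 156) % 312] ^ xA;
    }
    idx_ = 0;
  }

  static void tables() {
    if (tables_ready_) return;
    const double m = 2147483648.0, vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn_[0] = (uint32_t)((dn / q) * m);
    kn_[1] = 0;
    wn_[0] = q / m;
    wn_[127] = dn / m;
    fn_[0] = 1.0;
    fn_[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn_[i + 1] = (uint32_t)((dn / tn) * m);
      tn = dn;
      fn_[i] = std::exp(-0.5 * dn * dn);
      wn_[i] = dn / m;
    }
    tables_ready_ = true;
  }

  uint64_t mt_[312];
  int idx_;
  bool have_spare_;
  double spare_;
  static uint32_t kn_[128];
  static double wn_[128], fn_[128];
  static bool tables_ready_;
};

#endif
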