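// Fused Brownian-dynamics / photon-emission kernel.
//
// Per step and particle: add a Gaussian displacement of per-axis variance
// 2*D*dt, apply the boundary rules, then emit a photon with probability
// brightness * W(position) (Bernoulli thinning).  Counts are binned per
// step.  The RNG is a self-contained xoshiro256++ with polar Box-Muller
// normals so that a run is a pure function of its 64-bit seed, independent
// of R's RNG state and fast enough for ~1e10 particle-steps.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
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
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// 128-layer ziggurat for the standard normal (Marsaglia & Tsang layout,
// tables built at construction): ~99% of draws cost one RNG word, one
// compare and one multiply.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;  // 2^31
    const double vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

struct NormalRng {
  Xoshiro rng;
  const Ziggurat& zig;
  NormalRng(uint64_t seed, const Ziggurat& z) : rng(seed), zig(z) {}
  inline double unif() { return rng.unif(); }
  double norm() {
    for (;;) {
      const int32_t hz = (int32_t)(uint32_t)rng.next();
      const int iz = hz & 127;
      const uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < zig.kn[iz]) return hz * zig.wn[iz];
      if (iz == 0) {  // tail beyond +-3.4426
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(1.0 - rng.unif()) / r;
          y = -std::log(1.0 - rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      const double x = hz * zig.wn[iz];
      if (zig.fn[iz] + rng.unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

static const Ziggurat kZiggurat;

struct GridProfile {
  const double *x, *y, *z, *v;
  int nx, ny, nz;
  int order;
  static inline int locate(const double* ax, int n, double p) {
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (p < ax[mid]) hi = mid; else lo = mid;
    }
    return lo;
  }
  inline double eval(double px, double py, double pz) const {
    if (px < x[0] || px > x[nx - 1] || py < y[0] || py > y[ny - 1] ||
        pz < z[0] || pz > z[nz - 1]) return 0.0;
    int ix = locate(x, nx, px), iy = locate(y, ny, py), iz = locate(z, nz, pz);
    double tx = (px - x[ix]) / (x[ix + 1] - x[ix]);
    double ty = (py - y[iy]) / (y[iy + 1] - y[iy]);
    double tz = (pz - z[iz]) / (z[iz + 1] - z[iz]);
    if (order == 0) {
      ix += tx > 0.5; iy += ty > 0.5; iz += tz > 0.5;
      return v[ix + nx * (iy + (size_t)ny * iz)];
    }
    double acc = 0.0;
    for (int dx = 0; dx <= 1; ++dx)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dz = 0; dz <= 1; ++dz) {
          double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                     (dz ? tz : 1 - tz);
          acc += w * v[(ix + dx) + nx * ((iy + dy) + (size_t)ny * (iz + dz))];
        }
    return acc;
  }
};

// Analytic profiles with a cheap cutoff: exp(e) with e < -36 is below 2e-16
// and treated as 0 to spare the exp() call on the (dominant) far-field
// population.
inline double w_gauss3d(double x, double y, double z, double r0, double z0) {
  const double e = -2.0 * (x * x + y * y) / (r0 * r0) -
                   2.0 * z * z / (z0 * z0);
  return e < -36.0 ? 0.0 : std::exp(e);
}
inline double w_nifs3d(double x, double y, double z, double r0, double z0) {
  if (z < 0) return 0.0;
  const double e = -2.0 * (x * x + y * y) / (r0 * r0) - z / z0;
  return e < -36.0 ? 0.0 : std::exp(e);
}
inline double w_annular(double x, double y, double a0, double b0) {
  const double d = (std::sqrt(x * x + y * y) - a0) / b0;
  const double e = -d * d;
  return e < -36.0 ? 0.0 : std::exp(e);
}

inline double wrap_center(double x, double L) {
  // periodic wrap onto [-L/2, L/2)
  if (x >= -0.5 * L && x < 0.5 * L) return x;
  return x - L * std::floor(x / L + 0.5);
}

}  // namespace

// [[Rcpp::export(name = ".sim_kernel")]]
Rcpp::List sim_kernel(int profile_id, Rcpp::List pars, bool mode2d,
                      Rcpp::NumericVector box, double z_plane,
                      int n_particles, double D, double dt, double n_steps_d,
                      double brightness, bool reflect_bottom, bool reflect_top,
                      double seed_d, bool return_positions) {
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  if (n_particles < 1) Rcpp::stop("n_particles must be >= 1");
  if (brightness < 0 || brightness > 0.1)
    Rcpp::stop("brightness must lie in [0, 0.1] (Bernoulli validity)");
  const double Lx = box[0], Ly = box[1];
  const double Lz = mode2d ? 0.0 : box[2];
  const double sigma = std::sqrt(2.0 * D * dt);
  if (6.0 * sigma > Lx || 6.0 * sigma > Ly || (!mode2d && 6.0 * sigma > Lz))
    Rcpp::stop("step size sqrt(2 D dt) is not small versus the box");

  double r0 = 0, z0 = 0, a0 = 0, b0 = 0;
  GridProfile gp{};
  Rcpp::NumericVector gx, gy, gz, gv;  // keep grid memory alive
  switch (profile_id) {
    case 1: case 2:
      r0 = Rcpp::as<double>(pars["r0"]);
      z0 = Rcpp::as<double>(pars["z0"]);
      break;
    case 3:
      a0 = Rcpp::as<double>(pars["a0"]);
      b0 = Rcpp::as<double>(pars["b0"]);
      break;
    case 4: {
      gx = pars["x"]; gy = pars["y"]; gz = pars["z"]; gv = pars["values"];
      gp.x = gx.begin(); gp.y = gy.begin(); gp.z = gz.begin();
      gp.v = gv.begin();
      gp.nx = gx.size(); gp.ny = gy.size(); gp.nz = gz.size();
      gp.order = Rcpp::as<int>(pars["order"]);
      break;
    }
    default: Rcpp::stop("unknown profile id");
  }

  NormalRng rng((uint64_t)seed_d, kZiggurat);
  std::vector<double> px(n_particles), py(n_particles), pz(n_particles);
  for (int i = 0; i < n_particles; ++i) {
    px[i] = (rng.unif() - 0.5) * Lx;
    py[i] = (rng.unif() - 0.5) * Ly;
    if (mode2d) pz[i] = z_plane;
    else pz[i] = reflect_bottom ? rng.unif() * Lz : (rng.unif() - 0.5) * Lz;
  }

  Rcpp::IntegerVector counts(n_steps);
  for (R_xlen_t t = 0; t < n_steps; ++t) {
    int c = 0;
    for (int i = 0; i < n_particles; ++i) {
      double x = px[i] + sigma * rng.norm();
      double y = py[i] + sigma * rng.norm();
      x = wrap_center(x, Lx);
      y = wrap_center(y, Ly);
      double z = pz[i];
      if (!mode2d) {
        z += sigma * rng.norm();
        if (reflect_bottom) {
          if (z < 0) z = -z;
          if (z > Lz) z = reflect_top ? 2.0 * Lz - z : z - Lz;
        } else {
          z = wrap_center(z, Lz);
        }
      }
      px[i] = x; py[i] = y; pz[i] = z;
      if (brightness > 0) {
        double w;
        switch (profile_id) {
          case 1: w = w_gauss3d(x, y, z, r0, z0); break;
          case 2: w = w_nifs3d(x, y, z, r0, z0); break;
          case 3: w = w_annular(x, y, a0, b0); break;
          default: w = gp.eval(x, y, z); break;
        }
        if (w > 0 && rng.unif() < brightness * w) ++c;
      }
    }
    counts[t] = c;
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("counts") = counts);
  if (return_positions) {
    Rcpp::NumericMatrix pos(n_particles, 3);
    for (int i = 0; i < n_particles; ++i) {
      pos(i, 0) = px[i]; pos(i, 1) = py[i]; pos(i, 2) = pz[i];
    }
    out["positions"] = pos;
  }
  return out;
}
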