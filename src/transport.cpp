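// Monte Carlo photon transport for FDOCT simulation.
//
// Layered medium, MCML-style weighted packets, small-angle two-component
// phase function, and ballistic guidance of unscattered packets along the
// wavefront normals of a focusing Gaussian beam. Single-step physics used by
// the kernel is also exported so the R test suite exercises the same code.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based deterministic RNG: per-photon xoshiro256** substreams seeded
// from (seed, photon index) through splitmix64, so results do not depend on
// scheduling order.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0x9E3779B97F4A7C15ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: safe for log()
  inline double unif() {
    return 1.0 - (next() >> 11) * 0x1.0p-53;
  }
};

// ---------------------------------------------------------------------------
// Geometry of the focusing Gaussian beam (4F sample arm)
// ---------------------------------------------------------------------------

struct Beam {
  double f, d, w0, lambda, n; // mm, mm, mm, mm (vacuum), medium index
  double ws;                  // 1/e intensity radius at tissue surface
  double wfp;                 // in-medium focal-plane radius w_f'
  double zR;                  // Rayleigh length in medium (1/e intensity convention)
  // signed inverse wavefront radius 1/R(z); smooth through the focus
  inline double invR(double z) const {
    double zeta = d - f + z / n;
    return -zeta / (zeta * zeta + zR * zR);
  }
  // unit tangent of the ballistic trajectory at (x, y, z)
  inline void dir(double x, double y, double z,
                  double &vx, double &vy, double &vz) const {
    double iR = invR(z);
    double tx = -x * iR, ty = -y * iR;
    double nrm = std::sqrt(1.0 + tx * tx + ty * ty);
    vx = tx / nrm; vy = ty / nrm; vz = 1.0 / nrm;
  }
};

static Beam beam_from_list(const List &g) {
  Beam b;
  b.f = as<double>(g["f"]); b.d = as<double>(g["d"]);
  b.w0 = as<double>(g["w0"]); b.lambda = as<double>(g["lambda"]);
  b.n = as<double>(g["n"]);
  b.ws = as<double>(g["ws"]); b.wfp = as<double>(g["wfp"]);
  b.zR = as<double>(g["zR"]);
  return b;
}

// ---------------------------------------------------------------------------
// Single-step physics
// ---------------------------------------------------------------------------

// Unpolarized Fresnel reflectance for incidence cosine cos_i (>= 0).
static double fresnel_R(double n1, double n2, double cos_i) {
  if (n1 == n2) return 0.0;
  if (cos_i > 1.0) cos_i = 1.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Sample (theta, phi) from the two-component small-angle phase function:
// with probability 2*pb theta ~ Uniform[0, pi]; otherwise theta^2 ~
// Exponential(2*(1-g)) truncated at pi by rejection.
static inline void sample_scatter(Rng &rng, double g, double pb,
                                  double &theta, double &phi) {
  double eps = rng.unif();
  if (eps < 2.0 * pb) {
    theta = M_PI * rng.unif();
  } else {
    double s2 = 2.0 * (1.0 - g);
    do {
      theta = std::sqrt(-s2 * std::log(rng.unif()));
    } while (theta > M_PI);
  }
  phi = 2.0 * M_PI * rng.unif();
}

// MCML direction update: deflect (ux,uy,uz) by polar angle theta, azimuth phi.
static inline void spin(double &ux, double &uy, double &uz,
                        double theta, double phi) {
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    double sgn = (uz >= 0) ? 1.0 : -1.0;
    ux = st * cp; uy = st * sp; uz = sgn * ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// One RK4 step of the ballistic trajectory ODE dr/ds = v(r), arc length h.
static inline void rk4_step(const Beam &b, double h,
                            double &x, double &y, double &z) {
  double k1x, k1y, k1z, k2x, k2y, k2z, k3x, k3y, k3z, k4x, k4y, k4z;
  b.dir(x, y, z, k1x, k1y, k1z);
  b.dir(x + 0.5 * h * k1x, y + 0.5 * h * k1y, z + 0.5 * h * k1z, k2x, k2y, k2z);
  b.dir(x + 0.5 * h * k2x, y + 0.5 * h * k2y, z + 0.5 * h * k2z, k3x, k3y, k3z);
  b.dir(x + h * k3x, y + h * k3y, z + h * k3z, k4x, k4y, k4z);
  x += h / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
  y += h / 6.0 * (k1y + 2 * k2y + 2 * k3y + k4y);
  z += h / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z);
}

// Local step cap: resolve the scale on which the wavefront curvature varies.
static inline double h_local(const Beam &b, double z, double h_cap) {
  double zeta = b.d - b.f + z / b.n;
  double scale = 0.1 * std::sqrt(zeta * zeta + b.zR * b.zR);
  return std::min(h_cap, std::max(scale, 1e-6));
}

// ---------------------------------------------------------------------------
// Exported single-step surfaces (used by R wrappers and the test suite)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_fresnel_reflectance(double n1, double n2, double cos_i) {
  return fresnel_R(n1, n2, cos_i);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_scatter(int n, double g, double pb, int seed) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    Rng rng((uint64_t)seed, (uint64_t)i);
    double th, ph;
    sample_scatter(rng, g, pb, th, ph);
    out(i, 0) = th; out(i, 1) = ph;
  }
  colnames(out) = CharacterVector::create("theta", "phi");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_direction(NumericMatrix dir, NumericVector theta,
                                   NumericVector phi) {
  int n = dir.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double ux = dir(i, 0), uy = dir(i, 1), uz = dir(i, 2);
    spin(ux, uy, uz, theta[i % theta.size()], phi[i % phi.size()]);
    out(i, 0) = ux; out(i, 1) = uy; out(i, 2) = uz;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_launch(int n, List geom, int seed) {
  Beam b = beam_from_list(geom);
  NumericMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    Rng rng((uint64_t)seed, (uint64_t)i);
    double r = b.ws * std::sqrt(-std::log(rng.unif()));
    double a = 2.0 * M_PI * rng.unif();
    double x = r * std::cos(a), y = r * std::sin(a);
    double vx, vy, vz;
    b.dir(x, y, 0.0, vx, vy, vz);
    out(i, 0) = x; out(i, 1) = y;
    out(i, 2) = vx; out(i, 3) = vy; out(i, 4) = vz;
  }
  colnames(out) = CharacterVector::create("x", "y", "ux", "uy", "uz");
  return out;
}

// Advance a ballistic packet a geometric arc length s from (x, y, z);
// returns end position and the wavefront-normal direction there.
// [[Rcpp::export]]
NumericVector cpp_ballistic_advance(NumericVector start, double s, List geom,
                                    double h_max) {
  Beam b = beam_from_list(geom);
  double x = start[0], y = start[1], z = start[2];
  double left = s;
  while (left > 0) {
    double h = std::min(left, h_local(b, z, h_max));
    rk4_step(b, h, x, y, z);
    left -= h;
  }
  double vx, vy, vz;
  b.dir(x, y, z, vx, vy, vz);
  return NumericVector::create(x, y, z, vx, vy, vz);
}

// Trace many ballistic packets from the surface down to depth z_target.
// [[Rcpp::export]]
NumericMatrix cpp_trace_to_depth(NumericMatrix xy, double z_target, List geom,
                                 double h_max) {
  Beam b = beam_from_list(geom);
  int n = xy.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double x = xy(i, 0), y = xy(i, 1), z = 0.0;
    int guard = 0;
    while (z < z_target && ++guard < 1000000) {
      double vx, vy, vz;
      b.dir(x, y, z, vx, vy, vz);
      double h = std::min(h_local(b, z, h_max), (z_target - z) / vz + 1e-12);
      rk4_step(b, h, x, y, z);
    }
    out(i, 0) = x; out(i, 1) = y;
  }
  return out;
}

// Accumulate S(k) = sum_i amp_i * exp(2 i k z_i) with Kahan compensation.
// [[Rcpp::export]]
ComplexVector cpp_accumulate_spectrum(NumericVector amp, NumericVector z,
                                      NumericVector k) {
  int m = k.size(), n = amp.size();
  ComplexVector out(m);
  for (int j = 0; j < m; ++j) {
    double sr = 0, si = 0, cr = 0, ci = 0;
    double kk = 2.0 * k[j];
    for (int i = 0; i < n; ++i) {
      double ph = kk * z[i];
      double tr = amp[i] * std::cos(ph) - cr;
      double ur = sr + tr; cr = (ur - sr) - tr; sr = ur;
      double ti = amp[i] * std::sin(ph) - ci;
      double ui = si + ti; ci = (ui - si) - ti; si = ui;
    }
    out[j].r = sr; out[j].i = si;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full transport loop
// ---------------------------------------------------------------------------

struct LayerC {
  double mu_s, mu_a, g, pb, n, z_top, z_bot;
  double mu_t() const { return mu_s + mu_a; }
};

// [[Rcpp::export]]
List cpp_run_transport(int n_photons, int seed, NumericMatrix layers,
                       double n_ambient, List geom, std::string launch_mode,
                       double w_threshold, double p_survive, double h_max,
                       double mirror_z, double mirror_refl) {
  Beam b = beam_from_list(geom);
  int nl = layers.nrow();
  std::vector<LayerC> L(nl);
  for (int i = 0; i < nl; ++i) {
    L[i] = {layers(i, 0), layers(i, 1), layers(i, 2), layers(i, 3),
            layers(i, 4), layers(i, 5), layers(i, 6)};
  }
  double depth = L[nl - 1].z_bot;
  bool has_mirror = R_finite(mirror_z);
  bool lens_launch = (launch_mode == "lens");

  double absorbed = 0, transmitted = 0, exited_top = 0, rouletted = 0;
  std::vector<double> ew, eopl, epath, ex, ey, eux, euy, euz;

  for (int ip = 0; ip < n_photons; ++ip) {
    Rng rng((uint64_t)seed, (uint64_t)ip);

    // launch at the surface from the Gaussian intensity with radius ws
    double r = b.ws * std::sqrt(-std::log(rng.unif()));
    double aang = 2.0 * M_PI * rng.unif();
    double x = r * std::cos(aang), y = r * std::sin(aang), z = 0.0;
    double w = 1.0, opl = 0.0, path = 0.0;
    double ux, uy, uz;
    b.dir(x, y, 0.0, ux, uy, uz);
    bool ballistic = true, alive = true;
    int il = 0;

    if (lens_launch && n_ambient != L[0].n) {
      // packet arrives through air; surface Fresnel decides entry
      // in-air wavefront normal: same construction with n = 1
      Beam ba = b; ba.n = 1.0;
      double wfa = ba.lambda * (ba.f - ba.d) / (2.0 * M_PI * ba.ws);
      ba.zR = 2.0 * M_PI * wfa * wfa / ba.lambda;
      double vx, vy, vz;
      ba.dir(x, y, 0.0, vx, vy, vz);
      double R = fresnel_R(n_ambient, L[0].n, vz);
      if (rng.unif() < R) {
        // specular surface reflection: exits immediately, zero path in medium
        ew.push_back(w); eopl.push_back(0.0); epath.push_back(0.0);
        ex.push_back(x); ey.push_back(y);
        eux.push_back(vx); euy.push_back(vy); euz.push_back(-vz);
        exited_top += w;
        continue;
      }
      // transmitted: ballistic guidance in the medium takes over below
    }

    double xi = -std::log(rng.unif()); // dimensionless optical depth budget

    // --- ballistic phase: curved trajectory along wavefront normals ---
    while (alive && ballistic) {
      double mu_t = L[il].mu_t();
      double vx, vy, vz;
      b.dir(x, y, z, vx, vy, vz);
      double h = h_local(b, z, h_max);
      if (mu_t > 0) h = std::min(h, xi / mu_t);
      // cap by distance to the lower/upper layer boundary along z
      double zb = L[il].z_bot;
      double to_b = (zb - z) / vz;
      bool hit_boundary = false, hit_mirror = false;
      if (has_mirror && mirror_z > z && mirror_z <= zb) {
        double to_m = (mirror_z - z) / vz;
        if (to_m <= h) { h = to_m; hit_mirror = true; }
      }
      if (!hit_mirror && to_b <= h) { h = to_b; hit_boundary = true; }
      rk4_step(b, h, x, y, z);
      opl += L[il].n * h; path += h;
      if (mu_t > 0) xi -= mu_t * h;

      if (hit_mirror) {
        z = mirror_z;
        if (rng.unif() < mirror_refl) {
          b.dir(x, y, z, vx, vy, vz);
          ux = vx; uy = vy; uz = -vz; // specular reflection
          ballistic = false;
        } else { // transmits through the reflector plane
          continue;
        }
      } else if (hit_boundary) {
        z = zb;
        if (il == nl - 1) {
          // bottom surface
          b.dir(x, y, z, vx, vy, vz);
          double R = fresnel_R(L[il].n, n_ambient, vz);
          if (rng.unif() < R) {
            ux = vx; uy = vy; uz = -vz; ballistic = false;
          } else { transmitted += w; alive = false; }
        } else {
          double n1 = L[il].n, n2 = L[il + 1].n;
          if (n1 == n2) { il += 1; }
          else {
            b.dir(x, y, z, vx, vy, vz);
            double R = fresnel_R(n1, n2, vz);
            if (rng.unif() < R) { ux = vx; uy = vy; uz = -vz; ballistic = false; }
            else {
              // refract; index mismatch ends beam guidance
              double st = n1 / n2 * std::sqrt(1.0 - vz * vz);
              double sc = (std::fabs(1.0 - vz * vz) < 1e-30)
                              ? 0.0
                              : st / std::sqrt(1.0 - vz * vz);
              ux = vx * sc; uy = vy * sc;
              uz = std::sqrt(std::max(0.0, 1.0 - st * st));
              ballistic = false; il += 1;
            }
          }
        }
      } else if (mu_t > 0 && xi <= 1e-12) {
        // first scattering event
        double mu_a = L[il].mu_a;
        if (mu_a > 0) {
          double dw = w * mu_a / mu_t;
          absorbed += dw; w -= dw;
        }
        b.dir(x, y, z, vx, vy, vz);
        ux = vx; uy = vy; uz = vz;
        double th, ph;
        sample_scatter(rng, L[il].g, L[il].pb, th, ph);
        spin(ux, uy, uz, th, ph);
        ballistic = false;
        xi = -std::log(rng.unif());
      }
    }

    // --- scattered phase: straight-line MCML-style transport ---
    int guard = 0;
    while (alive && ++guard < 100000000) {
      double mu_t = L[il].mu_t();
      if (std::fabs(uz) < 1e-14 && mu_t == 0) { absorbed += w; break; }
      // distance to the relevant z-plane along the current direction
      double zb = (uz > 0) ? L[il].z_bot : L[il].z_top;
      double db = (uz != 0) ? (zb - z) / uz : R_PosInf;
      // intervening mirror plane?
      bool to_mirror = false;
      if (has_mirror && mirror_z > L[il].z_top && mirror_z <= L[il].z_bot) {
        double dm = (uz != 0) ? (mirror_z - z) / uz : R_PosInf;
        if (dm > 1e-15 && dm < db &&
            ((uz > 0 && z < mirror_z) || (uz < 0 && z > mirror_z))) {
          db = dm; to_mirror = true;
        }
      }
      double s = (mu_t > 0) ? xi / mu_t : R_PosInf;
      if (s < db) {
        x += s * ux; y += s * uy; z += s * uz;
        opl += L[il].n * s; path += s;
        xi = 0;
        double mu_a = L[il].mu_a;
        if (mu_a > 0) {
          double dw = w * mu_a / mu_t;
          absorbed += dw; w -= dw;
        }
        if (w < w_threshold) {
          if (rng.unif() < p_survive) w /= p_survive;
          else { rouletted += w; break; }
        }
        double th, ph;
        sample_scatter(rng, L[il].g, L[il].pb, th, ph);
        spin(ux, uy, uz, th, ph);
        xi = -std::log(rng.unif());
      } else {
        x += db * ux; y += db * uy;
        opl += L[il].n * db; path += db;
        if (mu_t > 0) xi -= mu_t * db;
        if (to_mirror) {
          z = mirror_z;
          if (rng.unif() < mirror_refl) uz = -uz;
          continue;
        }
        z = zb;
        if (uz > 0) {
          if (il == nl - 1) {
            double R = fresnel_R(L[il].n, n_ambient, uz);
            if (rng.unif() < R) uz = -uz;
            else { transmitted += w; break; }
          } else {
            double n1 = L[il].n, n2 = L[il + 1].n;
            double R = fresnel_R(n1, n2, uz);
            if (rng.unif() < R) uz = -uz;
            else {
              if (n1 != n2) {
                double si2 = 1.0 - uz * uz;
                double st = n1 / n2 * std::sqrt(si2);
                double sc = (si2 < 1e-30) ? 0.0 : st / std::sqrt(si2);
                ux *= sc; uy *= sc;
                uz = std::sqrt(std::max(0.0, 1.0 - st * st));
              }
              il += 1;
            }
          }
        } else {
          if (il == 0) {
            // top surface: exit into the ambient medium?
            double n1 = L[0].n;
            double R = fresnel_R(n1, n_ambient, -uz);
            if (rng.unif() < R) uz = -uz;
            else {
              double si2 = 1.0 - uz * uz;
              double st = n1 / n_ambient * std::sqrt(si2);
              double sc = (si2 < 1e-30) ? 0.0 : st / std::sqrt(si2);
              double ax = ux * sc, ay = uy * sc;
              double az = -std::sqrt(std::max(0.0, 1.0 - st * st));
              ew.push_back(w); eopl.push_back(opl); epath.push_back(path);
              ex.push_back(x); ey.push_back(y);
              eux.push_back(ax); euy.push_back(ay); euz.push_back(az);
              exited_top += w;
              break;
            }
          } else {
            double n1 = L[il].n, n2 = L[il - 1].n;
            double R = fresnel_R(n1, n2, -uz);
            if (rng.unif() < R) uz = -uz;
            else {
              if (n1 != n2) {
                double si2 = 1.0 - uz * uz;
                double st = n1 / n2 * std::sqrt(si2);
                double sc = (si2 < 1e-30) ? 0.0 : st / std::sqrt(si2);
                ux *= sc; uy *= sc;
                uz = -std::sqrt(std::max(0.0, 1.0 - st * st));
              }
              il -= 1;
            }
          }
        }
      }
    }
  }

  int ne = (int)ew.size();
  NumericMatrix exits(ne, 8);
  for (int i = 0; i < ne; ++i) {
    exits(i, 0) = ew[i]; exits(i, 1) = eopl[i]; exits(i, 2) = epath[i];
    exits(i, 3) = ex[i]; exits(i, 4) = ey[i];
    exits(i, 5) = eux[i]; exits(i, 6) = euy[i]; exits(i, 7) = euz[i];
  }
  colnames(exits) = CharacterVector::create("weight", "opl", "path", "x", "y",
                                            "ux", "uy", "uz");
  NumericVector tally = NumericVector::create(
      _["launched"] = (double)n_photons, _["absorbed"] = absorbed,
      _["transmitted"] = transmitted, _["exited_top"] = exited_top,
      _["rouletted"] = rouletted);
  return List::create(_["exits"] = exits, _["tally"] = tally);
}
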