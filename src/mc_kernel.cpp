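// Photon-transport kernel for a homogeneous turbid slab with an oblique,
// profile-weighted incident beam and a surface pixel-grid detector.
//
// Conventions: z grows downward into the medium (surface at z = 0, bottom at
// z = thickness, both in mm); the incidence plane lies along +x; image column
// index grows with +x, row index with +y.  Free path lengths are sampled from
// the scattering coefficient only; absorption is applied as a terminal weight
// factor exp(-mu_a * L), which keeps the stored path statistics exactly
// rescalable to perturbed coefficients (perturbation MC).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// splitmix64 finalizer: bijective scramble used to derive substream states
inline uint64_t sm_mix(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// splitmix64, one independent substream per photon (counter-based seeding):
// the draw sequence of photon i depends only on (seed, i), which is what
// makes common-random-number re-simulation under perturbed coefficients
// strongly correlated per photon.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    return sm_mix(z);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

double hg_cosine(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// unpolarized Fresnel reflectance, incidence from medium n_i into n_t
double fresnel_unpol(double n_i, double n_t, double cos_i) {
  const double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  const double sin_t = n_i / n_t * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  const double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  const double rs = (n_i * cos_i - n_t * cos_t) / (n_i * cos_i + n_t * cos_t);
  const double rp = (n_i * cos_t - n_t * cos_i) / (n_i * cos_t + n_t * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// rotate direction (ux,uy,uz) by deflection ct and azimuth (cp, sp)
void spin(double &ux, double &uy, double &uz, double ct, double cp,
          double sp) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(uz) > 0.99999) {  // degenerate near-vertical branch
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    const double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    const double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
}

}  // namespace

// Returns a list with:
//   paths:  numeric matrix (n_detected x 5): exit x (mm), exit y (mm),
//           roulette-adjusted weight (absorption NOT applied), collision
//           count j, total path length L (mm)
//   energy: named vector: top, bottom, absorbed, roulette_killed,
//           roulette_gain, truncated (top/bottom/killed/truncated carry the
//           terminal factor exp(-mu_a*L); roulette_gain is the raw weight
//           added by survival boosts so that
//           n + gain = top + bottom + absorbed + killed + truncated exactly)
// [[Rcpp::export]]
List cpp_mc_transport(double mu_a, double mu_s, double g, double n_medium,
                      double n_above, double thickness,
                      NumericMatrix beam_w, int origin_row, int origin_col,
                      double pixel_scale, double incidence_deg,
                      double n_photons, double seed,
                      double roulette_threshold, double roulette_survival,
                      double max_events, bool pencil,
                      double lateral_kill_radius) {
  if (mu_s <= 0) stop("mu_s must be positive");
  if (n_medium < 1 || n_above < 1) stop("refractive indices must be >= 1");
  if (std::fabs(g) >= 1) stop("|g| must be < 1");

  const uint64_t seed0 =
      sm_mix(static_cast<uint64_t>(seed) * 0x2545F4914F6CDD1DULL +
             0x9E3779B9ULL);

  // launch direction: refract the oblique incident beam at the surface
  const double theta_i = incidence_deg * M_PI / 180.0;
  const double sin_t = std::sin(theta_i) * n_above / n_medium;
  if (sin_t >= 1.0) stop("incident beam is totally reflected");
  const double cos_t = std::sqrt(1.0 - sin_t * sin_t);

  // beam-pixel cumulative distribution (positive weights only)
  std::vector<double> cum;
  std::vector<int> pix;
  if (!pencil) {
    const int nr = beam_w.nrow(), nc = beam_w.ncol();
    double tot = 0.0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        const double w = beam_w(r, c);
        if (w < 0) stop("beam weights must be non-negative");
        if (w > 0) {
          tot += w;
          cum.push_back(tot);
          pix.push_back(c * nr + r);
        }
      }
    if (cum.empty()) stop("beam profile has zero total weight");
    for (auto &v : cum) v /= tot;
  }
  const int beam_nr = pencil ? 0 : beam_w.nrow();

  std::vector<double> ox, oy, ow, oj, oL;
  const long n = static_cast<long>(n_photons);
  ox.reserve(n / 2); oy.reserve(n / 2); ow.reserve(n / 2);
  oj.reserve(n / 2); oL.reserve(n / 2);

  double e_top = 0, e_bottom = 0, e_abs = 0, e_rk = 0, e_rg = 0, e_tr = 0;
  const bool matched_top = std::fabs(n_medium - n_above) < 1e-12;

  for (long ip = 0; ip < n; ++ip) {
    Rng rng(sm_mix(seed0 ^ (0xD1B54A32D192ED03ULL *
                            static_cast<uint64_t>(ip + 1))));
    // launch position (mm, relative to origin pixel center)
    double x, y;
    if (pencil) {
      x = 0.0; y = 0.0;
    } else {
      const double u = rng.unif();
      const size_t k =
          std::upper_bound(cum.begin(), cum.end(), u) - cum.begin();
      const size_t kk = std::min(k, cum.size() - 1);
      const int r = pix[kk] % beam_nr, c = pix[kk] / beam_nr;
      // jitter uniformly within the selected pixel
      x = (c + 1 - origin_col + (rng.unif() - 0.5)) * pixel_scale;
      y = (r + 1 - origin_row + (rng.unif() - 0.5)) * pixel_scale;
    }
    double z = 0.0;
    double ux = sin_t, uy = 0.0, uz = cos_t;
    double w = 1.0, L = 0.0;
    long j = 0;
    bool alive = true;
    // unbiased lateral roulette: photons far outside the detector are
    // unlikely to contribute; survivors are boosted and the shell expands
    double kill_r2 = (lateral_kill_radius > 0)
        ? lateral_kill_radius * lateral_kill_radius : R_PosInf;
    // roulette triggers when w*exp(-mu_a*L) < threshold, i.e. when L
    // exceeds this cached bound (updated on survival boosts)
    double L_trig = (mu_a > 0)
        ? (std::log(w) - std::log(roulette_threshold)) / mu_a : R_PosInf;

    while (alive) {
      double s = -std::log(1.0 - rng.unif()) / mu_s;
      // propagate, handling boundary crossings within this free path
      while (s > 0 && alive) {
        double tb = R_PosInf;
        if (uz < 0)      tb = -z / uz;
        else if (uz > 0) tb = (thickness - z) / uz;
        if (tb <= s) {
          x += ux * tb; y += uy * tb; z += uz * tb; L += tb; s -= tb;
          if (uz < 0) {  // top surface
            z = 0.0;
            const double ci = -uz;
            const double R =
                matched_top ? 0.0 : fresnel_unpol(n_medium, n_above, ci);
            if (R < 1.0) {
              // deposit the refracted fraction at every crossing (weight
              // splitting): each crossing contributes deterministically,
              // which sharply reduces tail variance relative to a
              // probabilistic exit decision; the Fresnel factor is
              // independent of mu_a/mu_s, so pMC rescaling stays exact
              const double w_out = w * (1.0 - R);
              const double ew = w_out * std::exp(-mu_a * L);
              e_top += ew;
              e_abs += w_out - ew;
              ox.push_back(x); oy.push_back(y); ow.push_back(w_out);
              oj.push_back(static_cast<double>(j)); oL.push_back(L);
              w *= R;
              if (w <= 0) { alive = false; }
              else {
                uz = -uz;
                L_trig = (mu_a > 0)
                    ? (std::log(w) - std::log(roulette_threshold)) / mu_a
                    : R_PosInf;
                // immediate roulette if the surviving fraction is tiny
                if (w * std::exp(-mu_a * L) < roulette_threshold) {
                  if (rng.unif() < roulette_survival) {
                    e_rg += w * (1.0 / roulette_survival - 1.0);
                    w /= roulette_survival;
                    L_trig = (mu_a > 0)
                        ? (std::log(w) - std::log(roulette_threshold)) / mu_a
                        : R_PosInf;
                  } else {
                    const double ew2 = w * std::exp(-mu_a * L);
                    e_rk += ew2;
                    e_abs += w - ew2;
                    alive = false;
                  }
                }
              }
            } else {
              uz = -uz;  // total internal reflection
            }
          } else {       // bottom: matched-index escape, discarded
            const double ew = w * std::exp(-mu_a * L);
            e_bottom += ew;
            e_abs += w - ew;
            alive = false;
          }
        } else {
          x += ux * s; y += uy * s; z += uz * s; L += s; s = 0;
        }
      }
      if (!alive) break;

      // scattering event
      ++j;
      if (j > static_cast<long>(max_events)) {
        const double ew = w * std::exp(-mu_a * L);
        e_tr += ew;
        e_abs += w - ew;
        break;
      }
      const double ct = hg_cosine(g, rng.unif());
      // uniform azimuth via Marsaglia rejection (no trig calls)
      double cp, sp;
      for (;;) {
        const double v1 = 2.0 * rng.unif() - 1.0;
        const double v2 = 2.0 * rng.unif() - 1.0;
        const double r2 = v1 * v1 + v2 * v2;
        if (r2 < 1.0 && r2 > 0.0) {
          cp = (v1 * v1 - v2 * v2) / r2;
          sp = 2.0 * v1 * v2 / r2;
          break;
        }
      }
      spin(ux, uy, uz, ct, cp, sp);
      if ((j & 63L) == 0L) {  // periodic renormalization of the direction
        const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
      }

      if (x * x + y * y > kill_r2) {
        if (rng.unif() < 0.2) {
          e_rg += w * 4.0;
          w *= 5.0;
          kill_r2 *= 2.25;  // next shell at 1.5x the radius
          L_trig = (mu_a > 0)
              ? (std::log(w) - std::log(roulette_threshold)) / mu_a
              : R_PosInf;
        } else {
          const double ew = w * std::exp(-mu_a * L);
          e_rk += ew;
          e_abs += w - ew;
          break;
        }
      }

      // Russian roulette on the effective (absorption-discounted) weight
      if (L > L_trig) {
        const double ew = w * std::exp(-mu_a * L);
        if (rng.unif() < roulette_survival) {
          e_rg += w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
          L_trig = (std::log(w) - std::log(roulette_threshold)) / mu_a;
        } else {
          e_rk += ew;
          e_abs += w - ew;
          alive = false;
        }
      }
    }
  }

  const size_t m = ox.size();
  NumericMatrix paths(m, 5);
  for (size_t i = 0; i < m; ++i) {
    paths(i, 0) = ox[i]; paths(i, 1) = oy[i]; paths(i, 2) = ow[i];
    paths(i, 3) = oj[i]; paths(i, 4) = oL[i];
  }
  colnames(paths) = CharacterVector::create("x", "y", "weight_r", "j", "L");
  NumericVector energy = NumericVector::create(
      _["top"] = e_top, _["bottom"] = e_bottom, _["absorbed"] = e_abs,
      _["roulette_killed"] = e_rk, _["roulette_gain"] = e_rg,
      _["truncated"] = e_tr);
  return List::create(_["paths"] = paths, _["energy"] = energy);
}
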