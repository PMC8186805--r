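// Voxel Monte Carlo photon transport with a track-length fluence estimator.
//
// Free paths are sampled against the local scattering coefficient and the
// photon weight decays continuously by Beer-Lambert absorption along each
// voxel-traversal segment (albedo-weight scheme).  Deposited fluence per
// voxel and time gate is the exact path integral of the weight,
// integral w ds = w0 * (1 - exp(-mu_a s)) / mu_a,
// normalised per launched photon and per voxel volume (mm^-2).
// A tissue->air crossing triggers unpolarised Fresnel reflection (with
// total internal reflection) unless matched boundaries are requested.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const double C_MM_NS = 299.792458;  // speed of light in vacuum, mm/ns

// Deterministic, seedable PCG32 generator (O'Neill's minimal variant).
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform in (0,1): never returns 0 so -log(u) is always finite
  double u01() { return (static_cast<double>(next()) + 0.5) * 2.3283064365386963e-10; }
};

double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
  return c;
}

double fresnel_unpolarised(double n_in, double n_out, double ci) {
  if (ci < 0.0) ci = 0.0; else if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(1.0 - ci * ci);
  double st = n_in / n_out * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct);
  double rp = (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci);
  return 0.5 * (rs * rs + rp * rp);
}

void rotate_direction(double* d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.999999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = (uz >= 0.0) ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    d[2] = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
}

}  // namespace

// [[Rcpp::export(name = ".mc_hg_cos")]]
NumericVector mc_hg_cos(double g, NumericVector u) {
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// [[Rcpp::export(name = ".mc_fresnel")]]
double mc_fresnel(double n_in, double n_out, double cos_incident) {
  return fresnel_unpolarised(n_in, n_out, cos_incident);
}

// [[Rcpp::export(name = ".mc_simulate")]]
List mc_simulate(IntegerVector labels, IntegerVector dims, double h,
                 NumericVector mua_tab, NumericVector mus_tab,
                 NumericVector g_tab, NumericVector n_tab,
                 NumericVector p0, NumericVector d0,
                 double n_photons, double t_max, int n_gates,
                 double seed, double roulette_threshold, double survival_prob,
                 bool fresnel_boundary, bool keep_gates) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  const double gate_w = t_max / n_gates;
  const long np = static_cast<long>(n_photons);
  if (np < 1) stop("at least one photon must be launched");

  NumericVector fluence(keep_gates ? nvox * n_gates : nvox);
  NumericVector gate_totals(n_gates);
  double absorbed = 0.0, escaped = 0.0, alive = 0.0;
  double rkill = 0.0, rboost = 0.0;
  bool entered_any = false;

  Pcg32 rng(static_cast<uint64_t>(seed));

  double dir0[3] = {d0[0], d0[1], d0[2]};
  double nrm0 = std::sqrt(dir0[0]*dir0[0] + dir0[1]*dir0[1] + dir0[2]*dir0[2]);
  if (nrm0 <= 0) stop("launch direction must be non-zero");
  for (int a = 0; a < 3; ++a) dir0[a] /= nrm0;

  for (long ph = 0; ph < np; ++ph) {
    double pos[3] = {p0[0], p0[1], p0[2]};
    double dir[3] = {dir0[0], dir0[1], dir0[2]};
    double w = 1.0, t = 0.0, s_left = -std::log(rng.u01());

    int i = static_cast<int>(std::floor(pos[0] / h));
    int j = static_cast<int>(std::floor(pos[1] / h));
    int k = static_cast<int>(std::floor(pos[2] / h));
    // nudge on-boundary launches into the grid along the direction of travel
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
      for (int a = 0; a < 3; ++a) pos[a] += 1e-9 * dir[a];
      i = static_cast<int>(std::floor(pos[0] / h));
      j = static_cast<int>(std::floor(pos[1] / h));
      k = static_cast<int>(std::floor(pos[2] / h));
    }
    bool in_tissue_once = false;

    while (true) {
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
        escaped += w;
        break;
      }
      R_xlen_t idx = static_cast<R_xlen_t>(i) + nx * (static_cast<R_xlen_t>(j) + static_cast<R_xlen_t>(ny) * k);
      int lab = labels[idx];

      // distance to the voxel boundary along dir, and the crossing axis
      double db = R_PosInf; int axis = 0;
      for (int a = 0; a < 3; ++a) {
        if (dir[a] > 1e-12) {
          int cell = (a == 0) ? i : (a == 1) ? j : k;
          double d = ((cell + 1) * h - pos[a]) / dir[a];
          if (d < db) { db = d; axis = a; }
        } else if (dir[a] < -1e-12) {
          int cell = (a == 0) ? i : (a == 1) ? j : k;
          double d = (cell * h - pos[a]) / dir[a];
          if (d < db) { db = d; axis = a; }
        }
      }
      if (db < 0) db = 0;

      if (lab == 0) {
        // ballistic air traversal at vacuum speed; no interaction
        double seg = db + 1e-9;
        t += seg / C_MM_NS;
        if (t >= t_max) { alive += w; break; }
        for (int a = 0; a < 3; ++a) pos[a] += dir[a] * seg;
        if (axis == 0) i += (dir[0] > 0) ? 1 : -1;
        else if (axis == 1) j += (dir[1] > 0) ? 1 : -1;
        else k += (dir[2] > 0) ? 1 : -1;
        continue;
      }
      in_tissue_once = true; entered_any = true;

      double mua = mua_tab[lab], mus = mus_tab[lab];
      double gg = g_tab[lab], nn = n_tab[lab];
      double mus_eff = (mus > 1e-12) ? mus : 1e-12;
      double ds = s_left / mus_eff;
      double dmax_t = (t_max - t) * C_MM_NS / nn;
      double seg = ds; int event = 0;               // 0 scatter
      if (db < seg) { seg = db; event = 1; }        // 1 boundary
      if (dmax_t <= seg) { seg = dmax_t; event = 2; }  // 2 time cut

      // deposit exact weight integral over the segment
      double dep, e;
      if (mua > 1e-12) {
        e = std::expm1(-mua * seg);
        dep = -e * w / mua;
        absorbed += -e * w;
        w *= (1.0 + e);
      } else {
        dep = w * seg;
      }
      int gate = static_cast<int>(t / gate_w);
      if (gate >= n_gates) gate = n_gates - 1;
      if (keep_gates) fluence[idx + nvox * gate] += dep; else fluence[idx] += dep;
      gate_totals[gate] += dep;

      t += seg * nn / C_MM_NS;
      for (int a = 0; a < 3; ++a) pos[a] += dir[a] * seg;

      if (event == 2) { alive += w; break; }
      if (event == 0) {
        double ct = hg_cos(gg, rng.u01());
        double phi = 2.0 * M_PI * rng.u01();
        rotate_direction(dir, ct, phi);
        s_left = -std::log(rng.u01());
      } else {
        s_left -= seg * mus_eff;
        if (s_left < 0) s_left = 0;
        int ni = i, nj = j, nk = k;
        if (axis == 0) ni += (dir[0] > 0) ? 1 : -1;
        else if (axis == 1) nj += (dir[1] > 0) ? 1 : -1;
        else nk += (dir[2] > 0) ? 1 : -1;
        bool outside = (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz);
        int nlab = 0;
        if (!outside) {
          R_xlen_t nidx = static_cast<R_xlen_t>(ni) + nx * (static_cast<R_xlen_t>(nj) + static_cast<R_xlen_t>(ny) * nk);
          nlab = labels[nidx];
        }
        if (nlab == 0) {
          // tissue -> air interface
          double n_out_med = 1.0;
          bool reflect = false;
          if (fresnel_boundary && nn != n_out_med) {
            double ci = std::fabs(dir[axis]);
            double R = fresnel_unpolarised(nn, n_out_med, ci);
            reflect = (rng.u01() < R);
          }
          if (reflect) {
            dir[axis] = -dir[axis];
            // stay in the current voxel, on its face
          } else {
            escaped += w;
            break;
          }
        } else {
          // internal interfaces are index-matched (all tissue n equal)
          i = ni; j = nj; k = nk;
        }
      }

      if (w < roulette_threshold) {
        if (rng.u01() < survival_prob) {
          rboost += w * (1.0 / survival_prob - 1.0);
          w /= survival_prob;
        } else {
          rkill += w;
          break;
        }
      }
    }
    if (ph == 0 && !in_tissue_once) {
      stop("photon launched in air never reached tissue: check launch position/direction");
    }
  }
  if (!entered_any) stop("no photon reached tissue");

  // normalise per launched photon and per voxel volume
  double norm = 1.0 / (static_cast<double>(np) * h * h * h);
  for (R_xlen_t q = 0; q < fluence.size(); ++q) fluence[q] *= norm;

  return List::create(
    _["fluence"] = fluence,
    _["gate_totals"] = gate_totals,
    _["absorbed"] = absorbed,
    _["escaped"] = escaped,
    _["alive_at_tmax"] = alive,
    _["roulette_killed"] = rkill,
    _["roulette_boost"] = rboost,
    _["n_photons"] = static_cast<double>(np));
}
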