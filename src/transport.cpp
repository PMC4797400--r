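// Analog Monte Carlo estimation of S-factors on a labelled voxel grid.
//
// Physics model (deliberately simplified, documented in the package
// vignette):
//  * beta particles: energy from the tabulated spectrum, emitted
//    isotropically, deposited linearly along a straight track of CSDA range
//    in water; void voxels (label 0) are traversed without loss.
//  * photons: discrete lines, isotropic emission, Woodcock tracking with
//    water attenuation; photoelectric -> local absorption, incoherent
//    (Compton) -> Klein-Nishina scatter via Kahn's method with the recoil
//    electron absorbed locally; photons below the cutoff are absorbed
//    locally. Coherent scattering and bremsstrahlung are neglected.
// All voxels with label > 0 are water at the configured density.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct LogLogTable {
  std::vector<double> le, lv;
  void init(const NumericVector& e, const NumericVector& v) {
    le.resize(e.size()); lv.resize(v.size());
    for (int i = 0; i < e.size(); ++i) { le[i] = std::log(e[i]); lv[i] = std::log(v[i]); }
  }
  double at(double energy) const {
    double x = std::log(energy);
    if (x <= le.front()) x = le.front();
    if (x >= le.back())  x = le.back();
    size_t hi = std::lower_bound(le.begin(), le.end(), x) - le.begin();
    if (hi == 0) hi = 1;
    double t = (x - le[hi - 1]) / (le[hi] - le[hi - 1]);
    return std::exp(lv[hi - 1] + t * (lv[hi] - lv[hi - 1]));
  }
};

struct Grid {
  const int* lab; int nx, ny, nz; double vs; // mm
  int label_at(double x, double y, double z) const {
    // returns -1 outside the grid
    int i = (int)std::floor(x / vs), j = (int)std::floor(y / vs),
        k = (int)std::floor(z / vs);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return lab[(size_t)i + (size_t)nx * (j + (size_t)ny * k)];
  }
};

inline void iso_dir(std::mt19937_64& rng, std::uniform_real_distribution<double>& U,
                    double d[3]) {
  double c = 2.0 * U(rng) - 1.0, phi = 2.0 * M_PI * U(rng);
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = c;
}

// rotate direction d by polar angle (cost) about itself with random azimuth
inline void rotate_dir(std::mt19937_64& rng, std::uniform_real_distribution<double>& U,
                       double d[3], double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * U(rng), cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  double rho = std::sqrt(ux * ux + uy * uy);
  if (rho < 1e-12) {
    d[0] = sint * cphi; d[1] = sint * sphi; d[2] = cost * (uz >= 0 ? 1.0 : -1.0);
    return;
  }
  d[0] = cost * ux + sint * (ux * uz * cphi - uy * sphi) / rho;
  d[1] = cost * uy + sint * (uy * uz * cphi + ux * sphi) / rho;
  d[2] = cost * uz - sint * rho * cphi;
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

// Kahn's rejection method for the Klein-Nishina scattered-photon ratio
// x = E/E'; returns x, alpha = E in electron-mass units
inline double kahn_x(std::mt19937_64& rng, std::uniform_real_distribution<double>& U,
                     double alpha) {
  for (;;) {
    double u1 = U(rng), u2 = U(rng), u3 = U(rng);
    if (u1 <= (2.0 * alpha + 1.0) / (2.0 * alpha + 9.0)) {
      double x = 1.0 + 2.0 * alpha * u2;
      if (u3 <= 4.0 * (x - 1.0) / (x * x)) return x;
    } else {
      double x = (2.0 * alpha + 1.0) / (2.0 * alpha * u2 + 1.0);
      double cost = 1.0 - (x - 1.0) / alpha;
      if (u3 <= 0.5 * (cost * cost + 1.0 / x)) return x;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(IntegerVector labels, IntegerVector dims, double voxel_mm,
                  double density_g_cm3,
                  IntegerVector tally_ids,      // region ids to score
                  IntegerVector source_ids,     // region ids to run as sources
                  NumericVector beta_cdf_e,     // upper bin edges, keV
                  NumericVector beta_cdf,       // CDF at those edges (ends at yield)
                  NumericVector line_e, NumericVector line_i,
                  NumericVector xs_e, NumericVector xs_photo, NumericVector xs_incoh,
                  NumericVector cs_e, NumericVector cs_range_cm,
                  int n_histories, int n_batches, int seed, double cutoff_kev,
                  bool do_electrons, bool do_photons) {
  Grid g{labels.begin(), dims[0], dims[1], dims[2], voxel_mm};
  const int nt = tally_ids.size(), ns = source_ids.size();
  int max_id = 0;
  for (int i = 0; i < nt; ++i) max_id = std::max(max_id, tally_ids[i]);
  std::vector<int> row_of(max_id + 1, -1);
  for (int i = 0; i < nt; ++i) row_of[tally_ids[i]] = i;

  LogLogTable photo, incoh, total_xs, csda;
  photo.init(xs_e, xs_photo);
  incoh.init(xs_e, xs_incoh);
  {
    NumericVector tot(xs_e.size());
    for (int i = 0; i < xs_e.size(); ++i) tot[i] = xs_photo[i] + xs_incoh[i];
    total_xs.init(xs_e, tot);
  }
  csda.init(cs_e, cs_range_cm);

  // source voxel lists
  std::vector<std::vector<size_t>> src_vox(ns);
  size_t nvox = labels.size();
  for (size_t v = 0; v < nvox; ++v) {
    int l = labels[v];
    for (int s = 0; s < ns; ++s) if (l == source_ids[s]) src_vox[s].push_back(v);
  }
  for (int s = 0; s < ns; ++s)
    if (src_vox[s].empty())
      stop("empty source region (id %d)", (int)source_ids[s]);

  const double beta_yield = beta_cdf[beta_cdf.size() - 1];
  const int per_batch = n_histories / n_batches;
  NumericMatrix edep_mean(nt, ns), rel_unc(nt, ns);
  NumericVector emitted_kev(ns), deposited_kev(ns);

  for (int s = 0; s < ns; ++s) {
    std::mt19937_64 rng(1000003ULL * (unsigned long long)(seed + 7) + 31ULL * s);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    std::uniform_int_distribution<size_t> pick(0, src_vox[s].size() - 1);
    std::vector<std::vector<double>> batch(n_batches, std::vector<double>(nt, 0.0));
    double emit = 0.0, dep_all = 0.0;

    for (int b = 0; b < n_batches; ++b) {
      std::vector<double>& ed = batch[b];
      for (int h = 0; h < per_batch; ++h) {
        size_t v = src_vox[s][pick(rng)];
        size_t i = v % g.nx, j = (v / g.nx) % g.ny, k = v / ((size_t)g.nx * g.ny);
        double x0 = (i + U(rng)) * g.vs, y0 = (j + U(rng)) * g.vs,
               z0 = (k + U(rng)) * g.vs;

        if (do_electrons && U(rng) < beta_yield) {
          // inverse-CDF beta energy (uniform within the 1-keV bin)
          double u = U(rng) * beta_yield;
          size_t hi = std::lower_bound(beta_cdf.begin(), beta_cdf.end(), u) -
                      beta_cdf.begin();
          if (hi >= (size_t)beta_cdf.size()) hi = beta_cdf.size() - 1;
          double c0 = hi == 0 ? 0.0 : beta_cdf[hi - 1];
          double e_hi = beta_cdf_e[hi];
          double e_lo = hi == 0 ? 0.0 : beta_cdf_e[hi - 1];
          double E = e_lo + (e_hi - e_lo) * (u - c0) /
                     std::max(1e-300, beta_cdf[hi] - c0);
          emit += E;
          double d[3]; iso_dir(rng, U, d);
          double range_mm = 10.0 * csda.at(E) / density_g_cm3;
          double step = g.vs / 3.0;
          double x = x0, y = y0, z = z0, left = range_mm;
          while (left > 0.0) {
            double ds = std::min(step, left);
            double xm = x + d[0] * ds * 0.5, ym = y + d[1] * ds * 0.5,
                   zm = z + d[2] * ds * 0.5;
            int lab = g.label_at(xm, ym, zm);
            if (lab < 0) break;              // escaped the grid
            x += d[0] * ds; y += d[1] * ds; z += d[2] * ds;
            if (lab > 0) {                   // tissue: deposit, consume range
              double de = E * ds / range_mm;
              if (row_of.size() > (size_t)lab && row_of[lab] >= 0) ed[row_of[lab]] += de;
              dep_all += de;
              left -= ds;
            }
            // label 0 (air outside the animal): traverse without loss
          }
        }

        if (do_photons) {
          for (int l = 0; l < line_e.size(); ++l) {
            if (U(rng) >= line_i[l]) continue;
            double E = line_e[l];
            emit += E;
            double d[3]; iso_dir(rng, U, d);
            double x = x0, y = y0, z = z0;
            for (;;) {
              double mu_mm = total_xs.at(E) * density_g_cm3 / 10.0; // per mm
              double sfree = -std::log(1.0 - U(rng)) / mu_mm;
              x += d[0] * sfree; y += d[1] * sfree; z += d[2] * sfree;
              int lab = g.label_at(x, y, z);
              if (lab < 0) break;            // escape
              if (lab == 0) continue;        // Woodcock virtual collision in air
              double p_photo = photo.at(E) / total_xs.at(E);
              int row = (row_of.size() > (size_t)lab) ? row_of[lab] : -1;
              if (U(rng) < p_photo) {
                if (row >= 0) ed[row] += E;
                dep_all += E;
                break;
              }
              double alpha = E / 510.99895;
              double xr = kahn_x(rng, U, alpha);
              double Ep = E / xr;
              double de = E - Ep;
              if (row >= 0) ed[row] += de;
              dep_all += de;
              if (Ep < cutoff_kev) {
                if (row >= 0) ed[row] += Ep;
                dep_all += Ep;
                break;
              }
              rotate_dir(rng, U, d, 1.0 - (xr - 1.0) / alpha);
              E = Ep;
            }
          }
        }
      }
    }

    emitted_kev[s] = emit;
    deposited_kev[s] = dep_all;
    for (int t = 0; t < nt; ++t) {
      double m = 0.0, m2 = 0.0;
      for (int b = 0; b < n_batches; ++b) {
        double per = batch[b][t] / per_batch;
        m += per; m2 += per * per;
      }
      m /= n_batches;
      double var = std::max(0.0, m2 / n_batches - m * m) / (n_batches - 1);
      edep_mean(t, s) = m;                         // keV per decay
      rel_unc(t, s) = m > 0 ? std::sqrt(var) / m : NA_REAL;
    }
  }

  return List::create(_["edep_kev_per_decay"] = edep_mean,
                      _["rel_unc"] = rel_unc,
                      _["emitted_kev"] = emitted_kev,
                      _["deposited_kev"] = deposited_kev,
                      _["histories_per_source"] = per_batch * n_batches);
}
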