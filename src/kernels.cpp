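#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Depth-dose curve: quadratic build-up plateau (a + b (z/R)^2, tapered
// linearly to zero over [R, R + 2w]) plus a Gaussian Bragg peak of SD w at
// the range R, normalized to unit area so a spot's integral dose equals its
// MU when the kernel mass stays inside the grid.
static const double PLATEAU_A = 0.4;
static const double PLATEAU_B = 0.3;
static const double PEAK_AMP = 2.0;

static inline double depth_dose(double z, double R, double w, double inv_area) {
  if (z < 0.0) return 0.0;
  double val = 0.0;
  if (z <= R + 2.0 * w) {
    double taper = (z <= R) ? 1.0 : (R + 2.0 * w - z) / (2.0 * w);
    double zr = z / R;
    val += (PLATEAU_A + PLATEAU_B * zr * zr) * taper;
  }
  double dz = z - R;
  val += PEAK_AMP * std::exp(-dz * dz / (2.0 * w * w));
  return val * inv_area;
}

static double depth_dose_area(double R, double w) {
  double a = PLATEAU_A, b = PLATEAU_B;
  double plateau = (a + b / 3.0) * R;
  double taper = (a + b) * w + (4.0 * b / 3.0) * (w * w / R) +
                 (2.0 * b / 3.0) * (w * w * w / (R * R));
  double peak = PEAK_AMP * w * std::sqrt(2.0 * M_PI);
  return plateau + taper + peak;
}

// Superpose pencil-beam kernels of one field onto voxels given in the
// field's beam frame: u/v transverse coordinates and water-equivalent depth
// per voxel. Accumulates into `dose` in place.
// [[Rcpp::export]]
void cpp_superpose(NumericVector dose,
                   NumericVector u, NumericVector v, NumericVector depth,
                   NumericVector spot_u, NumericVector spot_v,
                   NumericVector spot_mu, NumericVector spot_range,
                   double bragg_width, double sigma0, double sigma_growth,
                   double lateral_cutoff_sigmas) {
  const R_xlen_t nvox = dose.size();
  const R_xlen_t nspot = spot_u.size();
  for (R_xlen_t s = 0; s < nspot; ++s) {
    const double su = spot_u[s], sv = spot_v[s], mu = spot_mu[s];
    const double R = spot_range[s];
    const double inv_area = 1.0 / depth_dose_area(R, bragg_width);
    const double zmax = R + 4.0 * bragg_width;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      const double z = depth[i];
      if (z < 0.0 || z > zmax) continue;
      const double sig = sigma0 + sigma_growth * z;
      const double du = u[i] - su, dv = v[i] - sv;
      const double r2 = du * du + dv * dv;
      const double cut = lateral_cutoff_sigmas * sig;
      if (r2 > cut * cut) continue;
      const double lat = std::exp(-r2 / (2.0 * sig * sig)) /
                         (2.0 * M_PI * sig * sig);
      dose[i] += mu * depth_dose(z, R, bragg_width, inv_area) * lat;
    }
  }
}

struct Offset {
  double dx, dy, dz, dist2norm;
};

static inline bool trilinear(const double *vals, const int *dim,
                             const double *origin, const double *spacing,
                             double x, double y, double z, double *out) {
  double g[3] = {(x - origin[0]) / spacing[0],
                 (y - origin[1]) / spacing[1],
                 (z - origin[2]) / spacing[2]};
  int i0[3];
  double f[3];
  for (int a = 0; a < 3; ++a) {
    if (g[a] < 0.0 || g[a] > dim[a] - 1) return false;
    i0[a] = (int)std::floor(g[a]);
    if (i0[a] > dim[a] - 2) i0[a] = dim[a] - 2;
    if (i0[a] < 0) i0[a] = 0;
    f[a] = g[a] - i0[a];
  }
  const int nx = dim[0], ny = dim[1];
  double acc = 0.0;
  for (int c = 0; c < 8; ++c) {
    const int ax = c & 1, ay = (c >> 1) & 1, az = (c >> 2) & 1;
    const double w = (ax ? f[0] : 1.0 - f[0]) *
                     (ay ? f[1] : 1.0 - f[1]) *
                     (az ? f[2] : 1.0 - f[2]);
    if (w == 0.0) continue;
    const R_xlen_t idx = (i0[0] + ax) +
                         (R_xlen_t)nx * ((i0[1] + ay) +
                         (R_xlen_t)ny * (i0[2] + az));
    acc += w * vals[idx];
  }
  *out = acc;
  return true;
}

// 3D global gamma index with low-dose cutoff, sub-voxel trilinear sampling
// on a lattice of step interp_fraction * dta within search_radius_factor *
// dta, and exact early exit: offsets are visited in order of increasing
// distance, so once the distance term alone reaches the current best
// gamma^2 no later offset can improve it.
// [[Rcpp::export]]
List cpp_gamma(NumericVector ref, IntegerVector ref_dim,
               NumericVector ref_origin, NumericVector ref_spacing,
               NumericVector ev, IntegerVector ev_dim,
               NumericVector ev_origin, NumericVector ev_spacing,
               double dose_percent, double dta, double cutoff_fraction,
               double interp_fraction, double normalization,
               double search_radius_factor, bool early_exit) {
  const double step = interp_fraction * dta;
  const double radius = search_radius_factor * dta;
  const int m = (int)std::floor(radius / step + 1e-9);

  std::vector<Offset> offs;
  offs.reserve((2 * m + 1) * (2 * m + 1) * (2 * m + 1) / 2);
  for (int i = -m; i <= m; ++i)
    for (int j = -m; j <= m; ++j)
      for (int k = -m; k <= m; ++k) {
        const double dx = i * step, dy = j * step, dz = k * step;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= radius * radius * (1.0 + 1e-12)) {
          offs.push_back({dx, dy, dz, d2 / (dta * dta)});
        }
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) {
              return a.dist2norm < b.dist2norm;
            });

  const double cutoff = cutoff_fraction * normalization;
  const double dd_denom = dose_percent / 100.0 * normalization;
  const int nx = ref_dim[0], ny = ref_dim[1], nz = ref_dim[2];
  NumericVector gamma((R_xlen_t)nx * ny * nz, NA_REAL);
  R_xlen_t n_eval = 0, n_pass = 0, n_no_sample = 0;

  const double *evp = REAL(ev);
  int evd[3] = {ev_dim[0], ev_dim[1], ev_dim[2]};
  double evo[3] = {ev_origin[0], ev_origin[1], ev_origin[2]};
  double evs[3] = {ev_spacing[0], ev_spacing[1], ev_spacing[2]};

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        // column-major order must match idx: recompute linear index
        const R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const double dr = ref[lin];
        if (dr < cutoff) continue;
        const double px = ref_origin[0] + i * ref_spacing[0];
        const double py = ref_origin[1] + j * ref_spacing[1];
        const double pz = ref_origin[2] + k * ref_spacing[2];
        double best2 = R_PosInf;
        bool sampled = false;
        for (size_t o = 0; o < offs.size(); ++o) {
          if (early_exit && offs[o].dist2norm >= best2) break;
          double de;
          if (!trilinear(evp, evd, evo, evs,
                         px + offs[o].dx, py + offs[o].dy, pz + offs[o].dz,
                         &de)) continue;
          sampled = true;
          const double dd = (de - dr) / dd_denom;
          const double g2 = offs[o].dist2norm + dd * dd;
          if (g2 < best2) best2 = g2;
        }
        ++n_eval;
        if (!sampled) ++n_no_sample;
        const double g = std::sqrt(best2);
        gamma[lin] = g;
        if (g <= 1.0) ++n_pass;
      }

  return List::create(
    _["gamma"] = gamma,
    _["n_evaluated"] = (double)n_eval,
    _["n_pass"] = (double)n_pass,
    _["n_no_sample"] = (double)n_no_sample);
}
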