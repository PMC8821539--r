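// Overdamped Langevin metadynamics core on a single distance-like CV.
//
// The bias potential is the running sum of deposited Gaussians.  Its force
// is accumulated on a fixed uniform grid (the usual sum_hills-style grid
// trick) and linearly interpolated during integration, so the per-step cost
// is independent of the number of kernels already deposited.  Kernels are
// truncated at 8 sigma from their center (relative value < 2e-14).
//
// Randomness is counter-based: the normal deviate at global step i is a pure
// function of (seed, i), so a continuation started at step n reproduces the
// tail of a longer single run bit for bit.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const double KB_KCAL = 1.987204259e-3; // kcal mol^-1 K^-1

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform in (0, 1]
static inline double u_closed(uint64_t r) {
  return ((r >> 11) + 1.0) * (1.0 / 9007199254740992.0);
}

// one standard normal per (key, counter) pair via Box-Muller
static inline double counter_normal(uint64_t key, uint64_t ctr) {
  uint64_t r1 = splitmix64(key ^ (2 * ctr + 1));
  uint64_t r2 = splitmix64(key ^ (2 * ctr + 2));
  double u1 = u_closed(r1);
  double u2 = u_closed(r2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// model potential forms (must mirror the R-side potential_energy())
//   0 flat, 1 harmonic_well, 2 piecewise_well_flat, 3 double_well
// params: [r_w, U0, kappa, r_w2, U02, kappa2]
static inline double pot_force(int form, const double* p, double D) {
  switch (form) {
  case 0:
    return 0.0;
  case 1:
    return -p[2] * (D - p[0]);
  case 2: {
    double rim = p[0] + std::sqrt(2.0 * p[1] / p[2]);
    return (D < rim) ? -p[2] * (D - p[0]) : 0.0;
  }
  case 3: {
    double rim1 = p[0] + std::sqrt(2.0 * p[1] / p[2]);
    double half2 = std::sqrt(2.0 * p[4] / p[5]);
    if (D < rim1) return -p[2] * (D - p[0]);
    if (std::fabs(D - p[3]) < half2) return -p[5] * (D - p[3]);
    return 0.0;
  }
  default:
    stop("unknown potential form code");
  }
  return 0.0; // unreached
}

// add one kernel's force contribution to the bias-force grid
static inline void deposit_on_grid(std::vector<double>& fgrid, double x0,
                                   double dx, double d, double sigma,
                                   double h) {
  double cut = 8.0 * sigma;
  int n = (int)fgrid.size();
  int i0 = (int)std::ceil((d - cut - x0) / dx);
  int i1 = (int)std::floor((d + cut - x0) / dx);
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
  double inv_s2 = 1.0 / (sigma * sigma);
  for (int i = i0; i <= i1; ++i) {
    double x = x0 + dx * i;
    double u = x - d;
    // F = -dV/dx of V = h exp(-u^2 / 2 sigma^2)
    fgrid[i] += h * u * inv_s2 * std::exp(-0.5 * u * u * inv_s2);
  }
}

static inline double grid_interp(const std::vector<double>& fgrid, double x0,
                                 double dx, double x) {
  int n = (int)fgrid.size();
  double t = (x - x0) / dx;
  if (t <= 0.0) return fgrid[0];
  if (t >= n - 1) return fgrid[n - 1];
  int i = (int)t;
  double w = t - i;
  return fgrid[i] * (1.0 - w) + fgrid[i + 1] * w;
}

// [[Rcpp::export]]
List metad_core(int form, NumericVector pot_params, double dt, double Dc,
                double temperature, int tau_steps, double height, double sigma,
                double wall, double wall_spring, double grid_x0,
                double grid_dx, int n_grid, NumericVector fgrid_init,
                double D0, double start_step, double n_steps, double seed,
                bool deposit, int record_stride) {
  if (n_grid < 2) stop("bias grid needs at least 2 nodes");
  std::vector<double> fgrid(n_grid, 0.0);
  if (fgrid_init.size() == n_grid)
    for (int i = 0; i < n_grid; ++i) fgrid[i] = fgrid_init[i];
  else if (fgrid_init.size() != 0)
    stop("fgrid_init length mismatch");

  const double* pp = REAL(pot_params);
  double kT = KB_KCAL * temperature;
  double mob = Dc / kT;                       // mobility, A^2 ps^-1 per kcal/mol
  double noise_amp = std::sqrt(2.0 * Dc * dt);
  uint64_t key = splitmix64((uint64_t)seed + 0x51ED270B2F6EULL);

  int64_t s0 = (int64_t)start_step;
  int64_t N = (int64_t)n_steps;
  int64_t n_dep = deposit ? (s0 + N) / tau_steps - s0 / tau_steps : 0;
  int64_t n_rec = (s0 + N) / record_stride - s0 / record_stride;

  NumericVector ker_t(n_dep), ker_c(n_dep);
  // +2: possible t = start record and off-stride final record
  NumericVector tr_t(n_rec + 2), tr_d(n_rec + 2);
  int64_t ik = 0, it = 0;

  double D = D0;
  if (s0 == 0) { tr_t[it] = 0.0; tr_d[it] = D; ++it; }

  for (int64_t i = s0 + 1; i <= s0 + N; ++i) {
    double F = pot_force(form, pp, D) + grid_interp(fgrid, grid_x0, grid_dx, D);
    if (D > wall) F += -wall_spring * (D - wall);
    double step = mob * F * dt + noise_amp * counter_normal(key, (uint64_t)i);
    if (std::fabs(step) > 10.0 * noise_amp)
      stop("divergent integration step (|dD| > 10 step-sigma); use a smaller dt");
    D += step;
    if (D < 0.0) D = -D; // reflective lower boundary
    if (deposit && i % tau_steps == 0) {
      ker_t[ik] = (double)i * dt;
      ker_c[ik] = D;
      ++ik;
      deposit_on_grid(fgrid, grid_x0, grid_dx, D, sigma, height);
    }
    if (i % record_stride == 0) {
      tr_t[it] = (double)i * dt;
      tr_d[it] = D;
      ++it;
    }
  }
  bool final_recorded = ((s0 + N) % record_stride == 0) && N > 0;
  if (!final_recorded) {
    tr_t[it] = (double)(s0 + N) * dt;
    tr_d[it] = D;
    ++it;
  }

  NumericVector fg(n_grid);
  for (int i = 0; i < n_grid; ++i) fg[i] = fgrid[i];
  return List::create(
      _["kernel_time"] = NumericVector(ker_t.begin(), ker_t.begin() + ik),
      _["kernel_center"] = NumericVector(ker_c.begin(), ker_c.begin() + ik),
      _["traj_time"] = NumericVector(tr_t.begin(), tr_t.begin() + it),
      _["traj_D"] = NumericVector(tr_d.begin(), tr_d.begin() + it),
      _["final_D"] = D, _["final_step"] = (double)(s0 + N),
      _["final_off_stride"] = !final_recorded, _["fgrid"] = fg);
}

// Rebuild the bias-force grid from a recorded kernel sequence, depositing in
// the recorded order so the floating-point state matches the original run.
// [[Rcpp::export]]
NumericVector rebuild_bias_grid(NumericVector centers, NumericVector widths,
                                NumericVector heights, double grid_x0,
                                double grid_dx, int n_grid) {
  std::vector<double> fgrid(n_grid, 0.0);
  int n = centers.size();
  for (int k = 0; k < n; ++k)
    deposit_on_grid(fgrid, grid_x0, grid_dx, centers[k], widths[k],
                    heights[k]);
  return NumericVector(fgrid.begin(), fgrid.end());
}

// Exact (non-truncated) sum of Gaussian kernels evaluated at x.
// [[Rcpp::export]]
NumericVector sum_gaussians(NumericVector x, NumericVector centers,
                            NumericVector widths, NumericVector heights) {
  int nx = x.size(), nk = centers.size();
  NumericVector out(nx);
  for (int k = 0; k < nk; ++k) {
    double d = centers[k], inv2s2 = 0.5 / (widths[k] * widths[k]),
           h = heights[k];
    for (int i = 0; i < nx; ++i) {
      double u = x[i] - d;
      out[i] += h * std::exp(-u * u * inv2s2);
    }
  }
  return out;
}
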