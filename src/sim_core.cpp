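#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics inner loop of the trace simulator.
//
// Adds one species' expected per-bin detection intensity to `lambda`
// (n_bins x n_segments, modified in place): each of `n_molecules` walkers
// takes per-axis Gaussian steps of standard deviation `sd_step` in a
// periodic cubic box of edge `L`; the Gaussian detection profile
// exp(-2(dx^2+dy^2)/w_xy^2 - 2 dz^2/w_z^2) is evaluated at the
// minimum-image displacement from the box center, gated by an optional
// two-state (bright/dark) blinking chain with per-step switching
// probabilities T*(1-exp(-dt/tau_T)) and (1-T)*(1-exp(-dt/tau_T))
// (the exact discretization of the two-state CTMC).  `sub` substeps are
// accumulated per photon bin.  All randomness comes from R's RNG stream,
// so results are reproducible from set.seed() upstream.
// [[Rcpp::export]]
void sim_species_lambda(NumericMatrix lambda, int n_molecules, int sub,
                        double dt, double sd_step, double L,
                        double w_xy, double w_z, double brightness,
                        double triplet, double tau_T) {
  const int n_bins = lambda.nrow();
  const int n_seg = lambda.ncol();
  const double half = L / 2.0;
  const double cxy = 2.0 / (w_xy * w_xy);
  const double cz = 2.0 / (w_z * w_z);
  const bool blink = triplet > 0.0;
  const double q = blink ? 1.0 - std::exp(-dt / tau_T) : 0.0;
  const double p_bd = triplet * q;
  const double p_db = (1.0 - triplet) * q;
  const double eps = brightness * dt;

  for (int m = 0; m < n_molecules; ++m) {
    // positions are kept wrapped into [0, L) after every step (single
    // Brownian steps are far smaller than the box), so the displacement
    // from the box center is already the minimum image
    double x = unif_rand() * L;
    double y = unif_rand() * L;
    double z = unif_rand() * L;
    bool bright = blink ? (unif_rand() > triplet) : true;
    for (int s = 0; s < n_seg; ++s) {
      for (int b = 0; b < n_bins; ++b) {
        double acc = 0.0;
        for (int u = 0; u < sub; ++u) {
          x += norm_rand() * sd_step; if (x < 0) x += L; else if (x >= L) x -= L;
          y += norm_rand() * sd_step; if (y < 0) y += L; else if (y >= L) y -= L;
          z += norm_rand() * sd_step; if (z < 0) z += L; else if (z >= L) z -= L;
          if (blink) {
            const double r = unif_rand();
            if (bright) { if (r < p_bd) bright = false; }
            else        { if (r < p_db) bright = true;  }
          }
          if (!bright) continue;
          const double dx = x - half;
          const double dy = y - half;
          const double dz = z - half;
          const double arg = cxy * (dx * dx + dy * dy) + cz * dz * dz;
          if (arg < 30.0) acc += std::exp(-arg);  // below ~1e-13 otherwise
        }
        lambda(b, s) += eps * acc;
      }
    }
  }
}
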