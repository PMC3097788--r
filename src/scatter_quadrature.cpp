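// Deterministic single-scatter quadrature.
//
// Integrates exactly the estimand of the Monte Carlo transport model:
// incident rays and Compton exits confined to the central fan plane,
// with each contribution's out-of-plane azimuth mass spread over the
// detector rows by the shared arcsine row-window function
// (row_window.h).  The incident fan is partitioned at the bar edges so
// the blocker structure of the fluence is resolved at any stride; each
// ray's chord through the fill is integrated in steps with exact
// per-step attenuation integrals; the scattering-angle density is
// integrated channel bin by channel bin as seen from each interaction
// point.  The Klein-Nishina angular normalisation (sig_g) is computed
// in R on the same grid the Monte Carlo sampler uses.
//
// Units: geometry in mm, attenuation lengths in cm (mu in cm^-1),
// energies in keV.

#include <Rcpp.h>
#include <cmath>
#include "row_window.h"
using namespace Rcpp;

static const double ME_KEV = 510.99895;

// linear interpolation on the uniform fine energy grid, clamped
static inline double fine_mu(const double* mu, int n, double emin,
                             double estep, double e) {
  double x = (e - emin) / estep;
  if (x <= 0.0) return mu[0];
  if (x >= n - 1) return mu[n - 1];
  int i = (int)x;
  double w = x - i;
  return mu[i] * (1.0 - w) + mu[i + 1] * w;
}

// [[Rcpp::export]]
NumericMatrix scatter_quadrature_cpp(
    NumericVector ray_gamma, NumericVector ray_B, NumericVector ray_w,
    NumericVector ray_t0, NumericVector ray_t1, NumericVector ray_wallin_cm,
    NumericVector Eg, NumericVector fg,
    NumericVector muf_g, NumericVector muw_g,
    NumericVector muc_g, NumericVector sig_g,
    NumericVector mu_fine_fill, NumericVector mu_fine_wall,
    double efine_min, double efine_step,
    int n_rows, int n_channels, double pitch_rad,
    double rd_mm, double row_pitch_mm,
    double yc_mm, double r_fill_mm, double r_out_mm,
    double ds_mm, double w0) {

  const int n_rays = ray_gamma.size();
  const int ng = Eg.size();
  const int nfine = mu_fine_fill.size();
  const bool has_wall = r_out_mm > 0.0;
  const double* mff = mu_fine_fill.begin();
  const double* mfw = mu_fine_wall.begin();

  NumericMatrix out(n_rows, n_channels);
  RowWindowTable rtab(n_rows, row_pitch_mm);

  // channel-bin edge points on the detector arc
  std::vector<double> ex(n_channels + 1), ey(n_channels + 1);
  for (int i = 0; i <= n_channels; ++i) {
    const double g = (i - n_channels / 2.0) * pitch_rad;
    ex[i] = rd_mm * std::sin(g);
    ey[i] = rd_mm * std::cos(g);
  }

  std::vector<double> psi(n_channels + 1), wg(ng), alpha(ng), invsig(ng);
  for (int g = 0; g < ng; ++g) {
    alpha[g] = Eg[g] / ME_KEV;
    invsig[g] = 1.0 / sig_g[g];
  }

  for (int r = 0; r < n_rays; ++r) {
    const double sx = std::sin(ray_gamma[r]);
    const double sy = std::cos(ray_gamma[r]);
    const double L = ray_t1[r] - ray_t0[r];
    if (L <= 0.0) continue;
    const int nstep = std::max(1, (int)std::ceil(L / ds_mm));
    const double ds = L / nstep;

    for (int k = 0; k < nstep; ++k) {
      const double tmid = ray_t0[r] + (k + 0.5) * ds;
      const double a_cm = (k * ds) / 10.0;   // depth in fill at step start
      const double b_cm = ((k + 1) * ds) / 10.0;
      const double px = sx * tmid, py = sy * tmid;
      const double rx = px, ry = py - yc_mm; // relative to phantom centre
      const double rr = rx * rx + ry * ry;
      const double pp = px * px + py * py;

      // per-group weight: fluence x blocker x depth-step integral of
      // the Compton interaction density x incident wall attenuation
      for (int g = 0; g < ng; ++g) {
        const double muf = muf_g[g];
        wg[g] = w0 * ray_w[r] * ray_B[r] * fg[g] * (muc_g[g] / muf) *
          (std::exp(-muf * a_cm) - std::exp(-muf * b_cm)) *
          std::exp(-muw_g[g] * ray_wallin_cm[r]);
      }

      // exit-direction angles of every channel-bin edge seen from p
      for (int i = 0; i <= n_channels; ++i) {
        const double dx = ex[i] - px, dy = ey[i] - py;
        psi[i] = std::atan2(sx * dy - sy * dx, sx * dx + sy * dy);
      }

      for (int c = 0; c < n_channels; ++c) {
        // channel index increases clockwise as seen from p
        const double dpsi = psi[c] - psi[c + 1];
        if (dpsi <= 0.0) continue;
        const double pm = 0.5 * (psi[c] + psi[c + 1]);
        const double th = std::fabs(pm);
        const double ct = std::cos(th), stq = std::sin(th);
        if (stq <= 0.0) continue;
        // in-plane exit ray at angle pm from the incident direction
        const double cpm = std::cos(pm), spm = std::sin(pm);
        const double ux = sx * cpm - sy * spm;
        const double uy = sx * spm + sy * cpm;
        const double bq = ux * rx + uy * ry;
        double disc = bq * bq - (rr - r_fill_mm * r_fill_mm);
        if (disc < 0.0) disc = 0.0;
        const double lf_cm = (-bq + std::sqrt(disc)) / 10.0;
        double lw_cm = 0.0;
        if (has_wall) {
          double disco = bq * bq - (rr - r_out_mm * r_out_mm);
          if (disco < 0.0) disco = 0.0;
          lw_cm = (-bq + std::sqrt(disco)) / 10.0 - lf_cm;
          if (lw_cm < 0.0) lw_cm = 0.0;
        }
        // in-plane distance to the detector arc
        const double bq2 = px * ux + py * uy;
        double disc2 = bq2 * bq2 - (pp - rd_mm * rd_mm);
        if (disc2 < 0.0) disc2 = 0.0;
        const double tcross = -bq2 + std::sqrt(disc2);

        double tot = 0.0;
        for (int g = 0; g < ng; ++g) {
          const double kk = 1.0 / (1.0 + alpha[g] * (1.0 - ct));
          const double ep = Eg[g] * kk;
          const double kn = 0.5 * kk * kk * (kk + 1.0 / kk -
                                             (1.0 - ct * ct));
          const double att = std::exp(
            -(fine_mu(mff, nfine, efine_min, efine_step, ep) * lf_cm +
              fine_mu(mfw, nfine, efine_min, efine_step, ep) * lw_cm));
          // in-plane angular density: pdf_theta(|psi|) / 2
          tot += wg[g] * M_PI * kn * stq * invsig[g] * dpsi * att * ep;
        }

        const double *rw0, *rw1;
        double fw;
        rtab.locate(tcross * stq, rw0, rw1, fw);
        for (int j = 0; j < n_rows; ++j)
          out(j, c) += tot * (rw0[j] * (1.0 - fw) + rw1[j] * fw);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
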