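// Shared per-row deposit windows for the in-plane scatter model.
//
// A contribution leaving the central plane with exit z-slope set by
// zspread = (in-plane crossing distance) * sin(theta) lands at
// z = zspread * cos(phi) for uniform azimuth phi, i.e. with arcsine
// density over z.  Summing the z-offset mass over the 64 illuminated
// fan planes gives each detector row's share: a 64-wide moving window
// over the 127 offset bins.  Both the Monte Carlo tally and the
// quadrature oracle draw these row shares from one table, precomputed
// on a fine logarithmic zspread grid (relative step ~0.4%) and
// linearly interpolated, so the two estimators share the identical
// row-deposit function.

#ifndef CTSCATTER_ROW_WINDOW_H
#define CTSCATTER_ROW_WINDOW_H

#include <vector>
#include <cmath>

struct RowWindowTable {
  int nb, n_rows;
  double l0, dl, z_lo, z_hi;
  std::vector<double> wtab;   // nb x n_rows, row-major per bucket

  RowWindowTable(int n_rows_, double row_pitch) : nb(2048),
      n_rows(n_rows_) {
    const int n_off = 2 * n_rows - 1;
    std::vector<double> zedges(n_off + 1);
    for (int k = 0; k <= n_off; ++k)
      zedges[k] = (k - n_off / 2.0) * row_pitch;
    z_lo = 0.25 * row_pitch;
    z_hi = 2000.0;
    l0 = std::log(z_lo);
    dl = (std::log(z_hi) - l0) / (nb - 1);
    wtab.resize((size_t)nb * n_rows);
    std::vector<double> frac(n_off);
    for (int b = 0; b < nb; ++b) {
      const double inv = 1.0 / std::exp(l0 + b * dl);
      double prev = (zedges[0] * inv <= -1.0) ? -M_PI_2
                      : std::asin(zedges[0] * inv);
      for (int k = 0; k < n_off; ++k) {
        double x = zedges[k + 1] * inv;
        double a = (x <= -1.0) ? -M_PI_2
                     : (x >= 1.0 ? M_PI_2 : std::asin(x));
        frac[k] = (a - prev) / M_PI;
        prev = a;
      }
      double w = 0.0;
      for (int k = 0; k < n_rows; ++k) w += frac[k];
      for (int j = 0; j < n_rows; ++j) {
        wtab[(size_t)b * n_rows + j] = w;
        if (j + 1 < n_rows) w += frac[j + n_rows] - frac[j];
      }
    }
  }

  // interpolated pointers + weight for a given zspread
  inline void locate(double zspread, const double*& w0, const double*& w1,
                     double& fw) const {
    double z = zspread < z_lo ? z_lo : (zspread > z_hi ? z_hi : zspread);
    double zb = (std::log(z) - l0) / dl;
    int b0 = (int)zb;
    if (b0 > nb - 2) b0 = nb - 2;
    fw = zb - b0;
    w0 = &wtab[(size_t)b0 * n_rows];
    w1 = w0 + n_rows;
  }
};

#endif
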