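// Row tally for the Monte Carlo scatter estimator.
//
// Each accepted sub-path deposits `val` into its detector channel,
// spread over the 64 rows with the shared arcsine row-window weights
// (see row_window.h).  Also accumulates squared deposits for standard
// errors, per element and per channel row-band total.

#include <Rcpp.h>
#include "row_window.h"
using namespace Rcpp;

// [[Rcpp::export]]
List mc_tally_cpp(NumericVector val, IntegerVector chan,
                  NumericVector zspread, double row_pitch,
                  int n_rows, int n_channels) {
  const int n = val.size();
  NumericMatrix s(n_rows, n_channels), s2(n_rows, n_channels);
  NumericVector s_tot(n_channels), s2_tot(n_channels);
  RowWindowTable tab(n_rows, row_pitch);

  for (int i = 0; i < n; ++i) {
    const int c = chan[i];
    const double *w0, *w1;
    double fw;
    tab.locate(zspread[i], w0, w1, fw);
    double tot = 0.0;
    double* sc = &s(0, c);
    double* sc2 = &s2(0, c);
    const double v = val[i];
    for (int j = 0; j < n_rows; ++j) {
      const double d = v * (w0[j] * (1.0 - fw) + w1[j] * fw);
      sc[j] += d;
      sc2[j] += d * d;
      tot += d;
    }
    s_tot[c] += tot;
    s2_tot[c] += tot * tot;
  }
  return List::create(_["s"] = s, _["s2"] = s2,
                      _["s_tot"] = s_tot, _["s2_tot"] = s2_tot);
}
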