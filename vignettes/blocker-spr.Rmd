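---
title: "Measuring CT scatter with a lead blocker array: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CT scatter with a lead blocker array: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctscatter)
```

## The measurement problem

Scattered radiation pollutes the projection data of multi-slice CT
scanners, and the wider the detector aperture, the worse the pollution.
Designing corrective algorithms or better geometry requires knowing the
magnitude and spatial distribution of the scatter a scanner actually
collects.  The blocker-array method measures it directly: a
one-dimensional array of highly attenuating lead bars is mounted just
below the collimator, between the source and the object.  Detector
channels inside a bar's shadow receive (essentially) scatter alone,
while the open channels between shadows receive total radiation,
primary plus scatter.  From one pair of exposures the method
reconstructs, for every one of the 64 detector rows:

* the scatter profile $I_{sc}(c)$ over all 912 channels,
* the total profile $I_{tot}(c)$,
* the primary profile $I_p(c) = I_{tot}(c) - I_{sc}(c)$,
* the scatter-to-primary ratio $\mathrm{SPR}(c) = I_{sc}(c)/I_p(c)$, and
* the integrated SPR of the row, $\sum_c \mathrm{SPR}(c)$.

The scanner modelled is a 64-row system with 540 mm source-isocentre
and 950 mm source-detector distance, a 56° fan over 912 channels per
row (888 active + 24 reference elements), 0.625 mm row pitch at
isocentre, and the blocker plane 160 mm below the source, so a bar of
width $w$ casts a shadow of width $w \times 950/160 = 5.9375\,w$ on the
detector arc.  The bars are 3 mm thick lead; with the published
$\mu/\rho = 3.32\ \mathrm{cm^2/g}$ and $\rho = 11.3\ \mathrm{g/cm^3}$,
$\mu = 37.52\ \mathrm{cm^{-1}}$ and the bar transmission is
$e^{-37.52 \times 0.3} \approx 1.29\times10^{-5}$.  (A printed value of
$1.24394\times10^{-5}$ circulates for this quantity; it is inconsistent
with the exponential law at the quoted $\mu$ and thickness, and the
package follows the exponential.)

Because no scanner hardware is available to a package, the measurement
chain is paired with a physics-based acquisition simulator that
generates the raw frames the pipeline consumes.  Everything the
pipeline is tested against is simulated truth, not the published
hardware measurements; the published absolute values (integrated SPR of
219.5 down to 39.9 over 80-140 kVp on the physical scanner) are outside
what a desk simulation reproduces, and only the qualitative laws they
express - SPR falls with kVp, grows with phantom size, falls with air
gap, scatter dips between two lateral peaks - are asserted.

## The measurement algorithm

1. **Decalibration.**  The scanner's acquisition software multiplies
   detector readings by per-element calibration gains and compresses
   them into a 16-bit range.  `decalibrate()` inverts the gains (and
   the affine uint16 compression is inverted on reading), recovering
   raw readings.  The calibration model here is a stand-in - log-normal
   gains plus uint16 affine compression - declared, not inferred from
   any scanner.
2. **Blocker-scatter compensation.**  The acquisition is performed
   twice, with and without the phantom, blocker in place both times.
   `compensate_blocker_scatter()` subtracts the no-phantom frame on
   blocker-affected channels only, removing the small signal the
   blocker assembly itself contributes there; open channels, which
   carry the full primary flux in the no-phantom frame, are untouched.
3. **Shadow sampling.**  `sample_shadow_scatter()` averages each bar's
   fully covered (`shadow_core`) channels per row into one scatter
   sample at the shadow's centre channel.  Partially covered boundary
   channels plus a guard margin (default 2 channels) are labelled
   penumbra and excluded from everything.  The source is modelled as a
   point, so there is no geometric penumbra; the margin exists to keep
   interpolation away from edge channels.
4. **Interpolation.**  `interpolate_scatter()` passes a
   monotone-preserving piecewise cubic (Fritsch-Carlson) through the
   20 bar samples and evaluates it at all 912 channels, with constant
   extrapolation beyond the outermost bars and clamping at zero.  The
   monotone cubic reproduces linear data exactly and cannot overshoot
   into negative scatter; the historical method description says only
   "interpolated", so the kind is configurable in principle and this
   default is a design choice.
5. **Total, primary, SPR.**  `total_profile()` takes open channels
   directly and fills shadowed ones with the same interpolation scheme
   applied to the open-channel readings; `primary_profile()` subtracts;
   `spr_profile()` divides, masking channels whose primary falls below
   `primary_floor` (default $10^{-3}$) times the row maximum - without
   the floor, near-zero primaries at the fan edges of off-centred
   acquisitions blow the ratio up.  `integrated_spr()` sums a row's SPR
   with masked channels contributing zero, over all 912 channels.
   Rows are processed independently throughout.

`measure_spr()` runs the chain end to end and returns a classed object
with print/summary/plot methods; `run_study()` maps it over a manifest
of acquisition pairs.

## The acquisition simulator

**Primary.**  Beer-Lambert ray integrals: for channel $c$ with ray
path lengths $\ell_m(c)$ through each phantom material $m$,
$$I_p(c) = \frac{k\,\mathrm{mA}\,t\,\mathrm{kVp}^2}{N_{ch}}
  \sum_E f(E)\,E\,e^{-\sum_m \mu_m(E)\ell_m(c)}\;B(c),$$
with $f(E)$ the normalised spectrum, $E$ the energy-integrating
detector weight, and $B(c)$ the blocker factor (bar transmission on
fully covered channels, a linear edge fraction on boundary channels).
The tube output heuristic $k\,\mathrm{mA}\,t\,\mathrm{kVp}^2$ sets only
the absolute detector-unit scale, which SPR cancels.

**Spectrum.**  A Kramers bremsstrahlung shape, $f(E) \propto
(\mathrm{kVp}-E)/E$ per 1 keV bin from 10 keV, hardened by the
inherent filtration (3.25 mm Al + 0.1 mm Cu) through the attenuation
tables.  No characteristic tungsten lines: only kVp trends are ever
asserted, and the filtered Kramers shape carries those.  Mass
attenuation ships as plain-text tables on the standard 10-150 keV grid
(log-log interpolation between points; the lead K-edge at 88 keV is
carried as a bracketing point pair).

**Scatter.**  Single Compton scatter only.  A source photon with
energy from the spectrum and a stratified fan direction interacts once
inside the phantom fill, at a depth drawn with density proportional to
the local attenuation; the scattering angle follows the Klein-Nishina
distribution; the scattered contribution, weighted by the scattered
energy and the Compton fraction $\mu_C/\mu_{tot}$, reaches the detector
attenuated by the exit path through fill and wall.  Interactions in
the thin PMMA wall are neglected (it attenuates both ways but its
interaction volume is ~3% of the fill's); coherent scatter and
multiple scatter are excluded.  The blocker sits upstream of the
phantom, so it attenuates incident rays only - scattered photons
travelling toward the detector cannot recross it.

Two parts of the row (z) dimension are handled analytically.  The
out-of-plane azimuth only sets a scattered ray's z intercept, so each
sub-path's contribution is spread over z-offset bins with the exact
arcsine weights of a uniform azimuth.  And since the cone illuminates
all 64 row fans and the phantom is z-invariant, the per-row scatter is
the single-plane offset pattern summed over the 64 illuminated planes
(a convolution); the cone's own z divergence of about ±2° is neglected.
This plane-convolution model is what gives the simulated frames
realistic scatter-to-primary levels (central-channel SPR of a few
percent at 120 kVp for the 215 mm water phantom); a strictly
single-plane model under-illuminates the phantom by the number of
planes, and its scatter is then comparable to the $10^{-5}$ lead
leakage, which would corrupt the blocker compensation.

**Variance reduction.**  Each photon is split into a full factorial of
4 interaction-depth strata × 8 scattering-angle strata × both in-plane
azimuth signs, with energies stratified within channel blocks; all
sub-paths are unbiased samples of the same estimand, and per-element /
per-channel standard errors are accumulated from the squared deposits.
At the study budget of $10^6$ photons per acquisition this resolves the
roughly 1% integrated-SPR steps between neighbouring kVp settings.
The study fixtures additionally use common random numbers: every
acquisition of a sweep shares one seed, so between-arm differences
(the quantities the study's conclusions rest on) are estimated with
far less Monte Carlo variance than independent streams would give.

**The quadrature oracle.**  `simulate_scatter_deterministic()`
evaluates the identical estimand by deterministic quadrature - incident
fan partitioned at the exact bar edges (so the sharp forward-scatter
dips the blocker imprints on the scatter profile are resolved at any
stride), chord steps of `grid_resolution` mm with exact per-step
attenuation integrals, fluence-weighted energy groups, the
Klein-Nishina angular density integrated channel bin by channel bin as
seen from each interaction point, and the same arcsine row-window
function the Monte Carlo tally uses.  The Klein-Nishina angular
normalisation is computed once, on the same fixed grid, for both
estimators, so Monte Carlo and quadrature target the same quantity and
can be compared within Monte Carlo standard errors
(`mc_oracle_agreement()`; the per-channel variance estimate is pooled
over neighbouring channels because individual deposit weights are
heavy-tailed).  The quadrature resolution trades accuracy for time as
any quadrature does; the defaults hold its bias well below the
$10^6$-photon Monte Carlo noise.

## What the simulator does and does not emulate

Emulated: the two-exposure protocol; lead-bar shadows at 5.9375×
magnification with single-boundary-channel penumbra; kVp-dependent
scatter fractions; the two-peaked scatter profile of a centred
cylinder (exit attenuation is largest for scatter emerging behind the
phantom's centre); the air-gap effect under axial off-centring;
calibration gains and 16-bit compression; Poisson noise (optional,
seeded).

Not emulated: multiple scatter and coherent scatter (so absolute SPR
levels sit below hardware measurements); the bow-tie filter (the
measurements the method was designed for were made without it);
detector energy response, crosstalk, anti-scatter septa; focal-spot
size (point source); helical or rotating acquisitions; the
manufacturer's raw-file dialect (a documented open container is used)
and its true calibration factors.  Passing tests therefore demonstrate
that the measurement chain recovers what this forward model produces,
not that it reproduces any particular scanner's numbers.

## Numerical choices and degenerate inputs

* Channel indexing is 0-based internally; reports label rows 1-64 so
  the central row is row 32.  The fan centre falls between channels
  455 and 456 (0-based); whether it falls on or between channels is
  not fixed by the geometry's description, and the between-channels
  convention is used throughout.
* Bar width and spacing are not published; the default layout is 20
  bars of 2 mm width evenly spaced over the central 90% of the fan at
  the blocker plane, which leaves open channels between all shadows
  for total-profile sampling.  Bars outside the fan are a
  configuration error naming the bar.
* The 24 reference elements are the 12 outermost channels at each fan
  edge; they are carried through all matrices and included in the
  integrated SPR (the row sum is over all detectors of the row).
* Coverage fractions within $10^{-9}$ of 0 or 1 are snapped, so fully
  covered channels see exactly the published bar transmission.
* Attenuation lookups outside 10-150 keV are a domain error; scattered
  energies below 10 keV (possible for soft incident photons at large
  angles) clamp to the 10 keV table edge, where surviving
  contributions are negligible anyway.
* Monte Carlo with `n_photons = 0` returns exact zeros; a missing
  phantom is an error for scatter (there is nothing to scatter from)
  while primary simulation accepts it (air scan).
* `interpolate_scatter()` requires at least two samples at strictly
  increasing positions; an all-masked SPR row is a degenerate-input
  error at the profile level but integrates to 0 at the row level.

## Problem sizes

The shipped study designs use the study conditions: $10^6$ photons per
acquisition, {80, 100, 120, 140} kVp × {215 mm water at 100 mA, 300 mm
polypropylene at 200 mA}, 3 s exposures, and an axial off-centring
sweep at 120 kVp / 100 mA.  Unit tests run reduced photon budgets
(2×10^4 to 2×10^5) and coarser quadrature settings; the full-budget
runs live in the acceptance suite and in `scripts/acceptance.R`, which
regenerates every figure-level quantity from scratch.

## Known limitations

The kVp dependence of the integrated SPR in this single-scatter,
energy-integrating model is much weaker than on hardware (a few
percent over 80-140 kVp rather than a factor of five): most of the
hardware effect comes from multiple-scatter buildup and detector
response, both deliberately outside the model.  The trend direction is
nevertheless stable and is what the package asserts.  Likewise the
absolute integrated SPR values depend on the arbitrary tube-output
scale and on the plane-convolution illumination model and should be
read as internally consistent simulator units, not predicted
measurements.
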