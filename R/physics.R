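#' Compton-scattered photon energy
#'
#' `E' = E / (1 + (E/m_e c^2)(1 - cos theta))`.
#'
#' @param energy incident photon energy, keV (vectorised)
#' @param theta scattering angle, radians (vectorised)
#' @return scattered photon energy, keV; always `<= energy`
#' @export
compton_energy <- function(energy, theta) {
  if (any(energy <= 0)) stop("energy must be positive")
  energy / (1 + (energy / .const$electron_rest_keV) * (1 - cos(theta)))
}

#' Klein-Nishina differential cross-section
#'
#' Differential cross-section per electron for Compton scattering, in
#' units of r_e^2 per steradian:
#' `0.5 k^2 (k + 1/k - sin^2 theta)` with `k = E'/E`.
#' At `theta = 0` this is 1 (forward Thomson limit); for `E -> 0` it
#' reduces to the Thomson form `(1 + cos^2 theta)/2`.
#'
#' @inheritParams compton_energy
#' @export
klein_nishina <- function(energy, theta) {
  if (any(energy <= 0)) stop("energy must be positive")
  k <- compton_energy(energy, theta) / energy
  0.5 * k^2 * (k + 1 / k - sin(theta)^2)
}

# fixed angular grid shared by the cross-section quadrature and the
# Monte Carlo inverse-CDF sampler, so both routes use one normalisation
.kn_theta_grid <- function(n = 2048) seq(0, pi, length.out = n + 1)

#' Total Klein-Nishina cross-section per electron
#'
#' Numerical quadrature `2 pi int KN(theta) sin(theta) dtheta` on a fixed
#' fine grid, in units of r_e^2.  This same normalisation is used by the
#' Monte Carlo sampler and the deterministic quadrature so that the two
#' scatter estimators target the identical quantity.
#'
#' @param energy photon energies, keV (vectorised)
#' @export
kn_total_cross_section <- function(energy) {
  th <- .kn_theta_grid()
  vapply(energy, function(E) {
    f <- klein_nishina(E, th) * sin(th)
    2 * pi * sum((f[-1] + f[-length(f)]) / 2 * diff(th))
  }, numeric(1))
}

# cumulative distribution of the scattering angle at one energy,
# evaluated on the shared theta grid (for inverse-CDF sampling)
.kn_theta_cdf <- function(energy) {
  th <- .kn_theta_grid()
  f <- klein_nishina(energy, th) * sin(th)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(th)))
  cdf / cdf[length(cdf)]
}

#' Polychromatic x-ray tube spectrum
#'
#' Bremsstrahlung-shaped fluence (Kramers form, per 1 keV bin
#' proportional to `(kVp - E)/E`) hardened by a filtration stack via
#' [transmission()], then normalised to unit total fluence.  The energy
#' grid is 1 keV bins from 10 keV to the kVp endpoint; fluence below
#' 10 keV is treated as fully removed by the inherent filtration.
#'
#' @param kvp peak tube voltage, kV; must lie in [40, 150]
#' @param filtration list of `list(material, thickness_cm)` pairs; the
#'   default is the scanner's minimum inherent filtration of 3.25 mm
#'   aluminium plus 0.1 mm copper
#' @return an `xray_spectrum` with fields `kvp`, `energy` (keV) and
#'   `fluence` (relative photons per bin, summing to 1)
#' @export
xray_spectrum <- function(kvp,
                          filtration = list(list("aluminium", 0.325),
                                            list("copper", 0.010))) {
  if (!is.numeric(kvp) || length(kvp) != 1 || kvp < 40 || kvp > 150)
    stop("kvp must be a single value in [40, 150]")
  energy <- seq(10, floor(kvp))
  fl <- (kvp - energy) / energy
  for (f in filtration)
    fl <- fl * transmission(f[[1]], energy, f[[2]])
  keep <- fl > 0
  energy <- energy[keep]; fl <- fl[keep]
  structure(list(kvp = kvp, energy = energy, fluence = fl / sum(fl)),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum> %g kVp, %d bins %g-%g keV, mean %.1f keV\n",
              x$kvp, length(x$energy), min(x$energy), max(x$energy),
              mean_energy(x)))
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum
#' @param spectrum an `xray_spectrum`
#' @return keV
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  sum(spectrum$energy * spectrum$fluence)
}
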