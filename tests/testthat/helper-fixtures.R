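# Shared fixture builders.  Everything is generated in code; the default
# scanner geometry is the studied 64 x 912 system, the "small" variants
# keep unit tests fast.

default_geom <- function() scanner_geometry()

water_phantom <- function(offset = 0) standard_phantom("water215", offset)

# a cheap but complete acquisition: full fan, modest photon budget
quick_setup <- function(kvp = 120, phantom = water_phantom(),
                        blocker = default_blocker_array(scanner_geometry()),
                        n_photons = 2e5, seed = 101, ma = 100,
                        noise = "off") {
  g <- scanner_geometry()
  acquisition_setup(g, phantom, blocker, xray_spectrum(kvp),
                    tube_current = ma, exposure_s = 3,
                    n_photons = n_photons, seed = seed, noise = noise)
}

# coarse quadrature settings for unit tests (acceptance uses defaults)
coarse_oracle <- function(setup, ds = 10)
  simulate_scatter_deterministic(setup, grid_resolution = ds,
                                 channel_stride = 24, n_energy_groups = 6)

# a single-line monoenergetic spectrum for hand-calculable primaries
mono_spectrum <- function(energy, kvp = energy + 1) {
  structure(list(kvp = kvp, energy = energy, fluence = 1),
            class = "xray_spectrum")
}
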