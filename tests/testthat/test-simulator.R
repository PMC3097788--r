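test_that("primary is flat without phantom or blocker and equals the spectral integral", {
  g <- default_geom()
  sp <- xray_spectrum(100)
  setup <- acquisition_setup(g, NULL, NULL, sp, tube_current = 100,
                             exposure_s = 3, n_photons = 0)
  p <- simulate_primary(setup)
  expect_equal(dim(p), c(64L, 912L))
  expected <- 10 * 100 * 3 * 100^2 / 912 * sum(sp$fluence * sp$energy)
  expect_equal(max(abs(p - expected)), 0)
})

test_that("blocker scales fully shadowed channels by the 3 mm lead transmission", {
  g <- default_geom()
  bl <- default_blocker_array(g)
  sp <- xray_spectrum(120)
  open <- acquisition_setup(g, NULL, NULL, sp, n_photons = 0)
  blocked <- acquisition_setup(g, NULL, bl, sp, n_photons = 0)
  p0 <- simulate_primary(open); p1 <- simulate_primary(blocked)
  mask <- project_shadow(g, bl, penumbra_margin = 0)
  core <- mask$labels == "shadow_core"
  openc <- mask$labels == "open"
  t_bar <- exp(-lead_blocker_attenuation() * 0.3)
  expect_equal(p1[, openc], p0[, openc])
  expect_equal(p1[, core] / p0[, core],
               matrix(t_bar, 64, sum(core)), tolerance = 1e-12)
})

test_that("monoenergetic primary through the water phantom matches a hand Beer-Lambert", {
  g <- default_geom()
  ph <- water_phantom()
  setup <- acquisition_setup(g, ph, NULL, mono_spectrum(60), n_photons = 0)
  p <- simulate_primary(setup)
  # channel 455 (0-based) sits half a pitch off the fan centre
  d <- 540 * sin((56 / 912) / 2 * pi / 180)
  chord <- function(R) 2 * sqrt(R^2 - d^2) / 10
  hand <- 10 * 100 * 3 * 61^2 / 912 * 60 *
    exp(-linear_attenuation("water", 60) * chord(107.5) -
          linear_attenuation("pmma", 60) * (chord(113.5) - chord(107.5)))
  expect_equal(p[32, 456], hand, tolerance = 1e-7)
})

test_that("Monte Carlo scatter is reproducible and zero for a zero budget", {
  setup <- quick_setup(n_photons = 5e4, seed = 31)
  a <- simulate_scatter_mc(setup)
  b <- simulate_scatter_mc(setup)
  expect_identical(a, b)
  setup2 <- quick_setup(n_photons = 5e4, seed = 32)
  expect_false(identical(simulate_scatter_mc(setup2)$scatter, a$scatter))
  empty <- quick_setup(n_photons = 0)
  z <- simulate_scatter_mc(empty)
  expect_equal(z$scatter, matrix(0, 64, 912))
  expect_equal(z$channel_total, numeric(912))
  no_ph <- acquisition_setup(default_geom(), NULL, NULL, xray_spectrum(120))
  expect_error(simulate_scatter_mc(no_ph), "phantom")
})

test_that("quadrature scatter is mirror symmetric and vanishes with the phantom", {
  setup <- quick_setup()
  det <- coarse_oracle(setup)
  expect_equal(det, det[nrow(det):1, ncol(det):1], tolerance = 1e-10)
  cols <- colSums(det)
  expect_lt(max(abs(cols - rev(cols))) / max(cols), 1e-3)
  tiny <- quick_setup(phantom = ct_phantom(2, "water"))
  det_tiny <- coarse_oracle(tiny)
  expect_lt(sum(det_tiny), sum(det) * 1e-3)
  expect_error(simulate_scatter_deterministic(setup, grid_resolution = -1),
               "grid_resolution")
})

test_that("quadrature is self-convergent in the chord step", {
  setup <- quick_setup()
  d1 <- simulate_scatter_deterministic(setup, grid_resolution = 10,
                                       channel_stride = 24,
                                       n_energy_groups = 6)
  d2 <- simulate_scatter_deterministic(setup, grid_resolution = 5,
                                       channel_stride = 24,
                                       n_energy_groups = 6)
  rel <- abs(colSums(d2) - colSums(d1)) / colSums(d2)
  expect_lt(max(rel), 0.01)
})

test_that("scatter fraction at the centre grows with phantom size and SPR scale is sane", {
  s_water <- quick_setup(n_photons = 0)
  s_poly <- quick_setup(phantom = standard_phantom("poly300"), n_photons = 0)
  d_w <- coarse_oracle(s_water); d_p <- coarse_oracle(s_poly)
  p_w <- simulate_primary(s_water); p_p <- simulate_primary(s_poly)
  sf_w <- d_w[32, 456] / (d_w[32, 456] + p_w[32, 456])
  sf_p <- d_p[32, 456] / (d_p[32, 456] + p_p[32, 456])
  expect_gt(sf_p, sf_w)
  expect_gt(sf_w, 0.01)   # scatter is a visible fraction at the centre
})

test_that("the water scatter profile dips between two lateral peaks", {
  setup <- quick_setup(n_photons = 0)
  det <- coarse_oracle(setup)
  centre <- mean(det[32, 456:457])
  expect_lt(centre, max(det[32, ]))
  # the peaks flank the centre inside the phantom shadow
  expect_true(which.max(det[32, ]) != 456)
})

test_that("rendered pairs conserve primary + scatter and are reproducible", {
  td <- withr::local_tempdir()
  setup <- quick_setup(n_photons = 4e4, seed = 17)
  paths <- render_acquisition_pair(setup, NULL, td, "t1")
  truth <- read_ground_truth(paths$truth)
  with_f <- read_frame(paths$with_phantom)
  without_f <- read_frame(paths$without_phantom)
  expect_equal(with_f$readings, truth$primary + truth$scatter,
               tolerance = 1e-6)
  expect_true(with_f$meta$phantom_present)
  expect_false(without_f$meta$phantom_present)
  expect_true(without_f$meta$blocker_present)
  # identical seeds give bit-identical outputs
  td2 <- withr::local_tempdir()
  paths2 <- render_acquisition_pair(setup, NULL, td2, "t1")
  expect_identical(unname(tools::md5sum(paths$with_phantom)),
                   unname(tools::md5sum(paths2$with_phantom)))
  expect_error(render_acquisition_pair(quick_setup(blocker = NULL),
                                       NULL, td), "blocker")
})

test_that("Poisson noise is seeded and perturbs the frames", {
  td <- withr::local_tempdir()
  setup <- quick_setup(n_photons = 2e4, seed = 23, noise = "poisson")
  p1 <- render_acquisition_pair(setup, NULL, td, "n1")
  p2 <- render_acquisition_pair(setup, NULL, withr::local_tempdir(), "n1")
  f1 <- read_frame(p1$with_phantom); f2 <- read_frame(p2$with_phantom)
  expect_identical(f1$readings, f2$readings)
  truth <- read_ground_truth(p1$truth)
  expect_false(isTRUE(all.equal(f1$readings,
                                truth$primary + truth$scatter)))
})

test_that("study fixtures enumerate the full design with a valid manifest", {
  td <- withr::local_tempdir()
  man <- make_study_fixtures(td, seed = 5, n_photons = 2e3,
                             kvps = c(80, 120), offsets = c(-50, 0, 50))
  # 2 kVp x 2 phantoms + 3 offsets = 7 pairs
  expect_equal(nrow(man), 7)
  files <- c(man$with_file, man$without_file, man$truth_file)
  expect_true(all(file.exists(file.path(td, files))))
  expect_true(file.exists(file.path(td, "manifest.tsv")))
  # same seed reproduces identical frames
  td2 <- withr::local_tempdir()
  make_study_fixtures(td2, seed = 5, n_photons = 2e3,
                      kvps = c(80, 120), offsets = c(-50, 0, 50))
  h1 <- unname(tools::md5sum(file.path(td, man$with_file)))
  h2 <- unname(tools::md5sum(file.path(td2, man$with_file)))
  expect_identical(h1, h2)
})
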