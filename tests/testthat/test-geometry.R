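test_that("channel fan angles sample the fan uniformly and antisymmetrically", {
  g <- default_geom()
  pitch <- 56 / 912
  expect_equal(channel_fan_angle(g, 455.5), 0)
  expect_equal(channel_fan_angle(g, 0), -28 + pitch / 2)
  expect_equal(channel_fan_angle(g, 911), 28 - pitch / 2)
  idx <- c(0, 17, 100, 455)
  expect_equal(channel_fan_angle(g, idx), -channel_fan_angle(g, 911 - idx))
  expect_equal(diff(channel_fan_angle(g, 0:911)), rep(pitch, 911))
  expect_error(channel_fan_angle(g, -1), "out of range")
  expect_error(channel_fan_angle(g, 912), "out of range")
})

test_that("geometry and phantom invariants are enforced", {
  expect_error(scanner_geometry(blocker_plane = 600), "blocker_plane")
  expect_error(scanner_geometry(fan_angle = -1), "fan_angle")
  expect_error(ct_phantom(-5, "water"), "fill_diameter")
  expect_error(ct_phantom(100, "water", wall_thickness = 3), "wall_material")
  # 300 mm phantom moved 300 mm toward the detector would hit it
  expect_error(
    acquisition_setup(default_geom(), standard_phantom("poly300", 300),
                      spectrum = xray_spectrum(120)),
    "intersect")
})

test_that("chord lengths follow the ray-cylinder closed form", {
  g <- default_geom()
  # central ray through the centred 215 mm water cylinder: full diameter
  cl <- chord_lengths(g, water_phantom(), 455.5)
  expect_equal(unname(cl["fill"]), 21.5)
  expect_equal(unname(cl["wall"]), 22.7 - 21.5)  # 6 mm wall both sides
  # ray at perpendicular distance R/2: chord = R sqrt(3)
  solid <- ct_phantom(215, "water")
  R <- 215 / 2
  gamma <- asin((R / 2) / 540) * 180 / pi
  ch <- gamma / (56 / 912) + 455.5
  expect_equal(unname(chord_lengths(g, solid, ch)["fill"]),
               R * sqrt(3) / 10, tolerance = 1e-10)
  # a clear miss returns zeros
  expect_equal(unname(chord_lengths(g, solid, 0)), c(0, 0))
})

test_that("chord lengths agree with a brute-force ray marcher", {
  g <- default_geom()
  ph <- water_phantom()
  set.seed(7)
  channels <- runif(25, 300, 611)       # rays that can intersect the phantom
  step_mm <- 0.01
  for (ch in channels) {
    gamma <- channel_fan_angle(g, ch) * pi / 180
    t <- seq(0, 950, by = step_mm)
    x <- sin(gamma) * t; y <- cos(gamma) * t
    r2 <- x^2 + (y - 540)^2
    marched_fill <- sum(r2 < (215 / 2)^2) * step_mm / 10
    marched_out <- sum(r2 < (227 / 2)^2) * step_mm / 10
    cl <- chord_lengths(g, ph, ch)
    expect_equal(unname(cl["fill"]), marched_fill, tolerance = 1e-3)
    expect_equal(unname(cl["fill"] + cl["wall"]), marched_out,
                 tolerance = 1e-3)
  }
})

test_that("bar shadows are magnified projections, mirror-symmetric for mirrored bars", {
  g <- default_geom()
  mask <- project_shadow(g, default_blocker_array(g))
  expect_equal(mask$magnification, 950 / 160)
  expect_equal(950 / 160, 5.9375)
  expect_equal(nrow(mask$bars), 20)
  # every channel has exactly one label; core and open disjoint by construction
  expect_true(all(mask$labels %in% c("shadow_core", "penumbra_margin", "open")))
  # two mirrored bars produce mirrored shadow-core intervals
  two <- blocker_array(c(-40, 40))
  m2 <- project_shadow(g, two, penumbra_margin = 0)
  expect_equal(m2$bars$core_first[1], 911 - m2$bars$core_last[2])
  expect_equal(m2$bars$core_last[1], 911 - m2$bars$core_first[2])
  # and each interval is contiguous with positive width
  expect_true(all(m2$bars$core_last >= m2$bars$core_first))
})

test_that("shadow cores match a dense sub-ray trace of the bar edges", {
  g <- default_geom()
  two <- blocker_array(c(-40, 40), bar_width = 2)
  m <- project_shadow(g, two, penumbra_margin = 0)
  pitch <- (56 / 912) * pi / 180
  nsub <- 400
  hit_frac <- vapply(0:911, function(i) {
    gam <- (((i - 456) + (seq_len(nsub) - 0.5) / nsub) * pitch)
    lat <- 160 * tan(gam)
    mean(abs(lat - (-40)) <= 1 | abs(lat - 40) <= 1)
  }, numeric(1))
  core_brute <- which(hit_frac > 1 - 1 / nsub) - 1L
  core_mask <- which(m$labels == "shadow_core") - 1L
  expect_equal(core_mask, core_brute)
})

test_that("shadow width grows with bar width and with projection magnification", {
  g <- default_geom()
  widths <- c(1, 2, 4)
  n_core <- vapply(widths, function(w) {
    m <- project_shadow(g, blocker_array(0, bar_width = w))
    sum(m$labels == "shadow_core")
  }, numeric(1))
  expect_true(all(diff(n_core) > 0))
  planes <- c(300, 200, 160, 120)   # closer blocker plane = larger magnification
  n_core2 <- vapply(planes, function(bp) {
    gi <- scanner_geometry(blocker_plane = bp)
    sum(project_shadow(gi, blocker_array(0, bar_width = 2))$labels ==
          "shadow_core")
  }, numeric(1))
  expect_true(all(diff(n_core2) >= 0) && tail(n_core2, 1) > n_core2[1])
})

test_that("invalid blocker layouts are rejected with the offending bar named", {
  g <- default_geom()
  expect_error(blocker_array(c(0, 1), bar_width = 2), "overlap")
  wide <- blocker_array(c(0, 160 * tan(28 * pi / 180)), bar_width = 2)
  expect_error(project_shadow(g, wide), "bar\\(s\\) 2")
})
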