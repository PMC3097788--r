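test_that("lead blocker attenuation reproduces the published constant", {
  # mu/rho = 3.32 cm^2/g at rho = 11.3 g/cm^3
  expect_equal(lead_blocker_attenuation(), 3.32 * 11.3)
  expect_equal(round(lead_blocker_attenuation(), 2), 37.52)
})

test_that("linear attenuation is table value times density at grid points", {
  expect_equal(linear_attenuation("lead", 60), 5.021 * 11.3)
  expect_equal(linear_attenuation("water", 100), 0.1707)
  expect_equal(linear_attenuation("pmma", 30), 0.3032 * 1.19)
  expect_error(linear_attenuation("water", 5), "outside the tabulated range")
  expect_error(linear_attenuation("water", 200), "outside the tabulated range")
})

test_that("water attenuation matches an independent elemental reconstruction", {
  # water from H (11.19%) and O (88.81%) elemental mass attenuation at 60 keV
  mu_rho_water_60 <- 0.1119 * 0.3260 + 0.8881 * 0.1904
  expect_equal(linear_attenuation("water", 60), mu_rho_water_60 * 1.0,
               tolerance = 0.01)
})

test_that("log-log interpolation stays within bracketing table values", {
  for (e in c(12, 27, 45, 72, 110)) {
    lo <- linear_attenuation("water", max(c(10, 15, 20, 30, 40, 50, 60, 80,
                                            100)[c(10, 15, 20, 30, 40, 50,
                                                   60, 80, 100) <= e]))
    hi <- linear_attenuation("water", min(c(15, 20, 30, 40, 50, 60, 80, 100,
                                            150)[c(15, 20, 30, 40, 50, 60,
                                                   80, 100, 150) >= e]))
    v <- linear_attenuation("water", e)
    expect_true(v <= lo && v >= hi)
  }
})

test_that("transmission follows the exponential law and is multiplicative", {
  expect_equal(transmission("water", 60, 0), 1.0)
  hvl <- log(2) / linear_attenuation("water", 60)
  expect_equal(transmission("water", 60, hvl), 0.5)
  # 3 mm of lead at the blocker constant: exp(-37.516 * 0.3)
  expect_equal(exp(-lead_blocker_attenuation() * 0.3), 1.291e-5,
               tolerance = 1e-3)
  t1 <- 0.7; t2 <- 1.9
  expect_equal(transmission("pmma", 45, t1 + t2),
               transmission("pmma", 45, t1) * transmission("pmma", 45, t2))
  expect_error(transmission("water", 60, -1), "nonnegative")
})

test_that("spectra are normalised, bounded by kVp, and harden with filtration", {
  for (kvp in c(80, 100, 120, 140)) {
    sp <- xray_spectrum(kvp)
    expect_equal(sum(sp$fluence), 1)
    expect_true(all(sp$energy <= kvp))
    expect_true(all(sp$fluence >= 0))
  }
  bare <- xray_spectrum(120, filtration = list())
  filt <- xray_spectrum(120)
  extra <- xray_spectrum(120, filtration = list(list("aluminium", 0.325),
                                                list("copper", 0.010),
                                                list("copper", 0.050)))
  expect_gt(mean_energy(filt), mean_energy(bare))
  expect_gt(mean_energy(extra), mean_energy(filt))
  expect_gt(mean_energy(xray_spectrum(140)), mean_energy(xray_spectrum(80)))
  expect_error(xray_spectrum(30), "kvp")
  expect_error(xray_spectrum(180), "kvp")
})

test_that("Compton kinematics follow the closed form", {
  expect_equal(compton_energy(80, 0), 80)
  expect_equal(compton_energy(511, pi / 2), 255.5, tolerance = 1e-3)
  expect_equal(compton_energy(100, pi), 100 / (1 + 200 / 511),
               tolerance = 1e-4)
  th <- seq(0, pi, length.out = 50)
  expect_true(all(compton_energy(70, th) <= 70))
})

test_that("Klein-Nishina kernel has the Thomson limits and forward peaking", {
  expect_equal(klein_nishina(100, 0), 1.0)
  th <- seq(0, pi, length.out = 30)
  expect_equal(klein_nishina(0.01, th), (1 + cos(th)^2) / 2,
               tolerance = 1e-4)
  # forward peaking: strictly decreasing out to 90 degrees, with the
  # global maximum at theta = 0 (beyond 90 degrees the cross-section
  # turns up again slightly at diagnostic energies)
  for (E in c(30, 60, 100, 140)) {
    v <- klein_nishina(E, seq(0.01, pi / 2, length.out = 100))
    expect_true(all(diff(v) < 0))
    full <- klein_nishina(E, seq(0, pi, length.out = 200))
    expect_equal(which.max(full), 1L)
  }
})

test_that("total Klein-Nishina cross-section matches the closed form", {
  closed_kn <- function(E) {
    eps <- E / 510.99895
    2 * pi * ((1 + eps) / eps^2 *
                (2 * (1 + eps) / (1 + 2 * eps) - log(1 + 2 * eps) / eps) +
                log(1 + 2 * eps) / (2 * eps) -
                (1 + 3 * eps) / (1 + 2 * eps)^2)
  }
  for (E in c(30, 60, 100, 140))
    expect_equal(kn_total_cross_section(E), closed_kn(E),
                 tolerance = 0.005)
})

test_that("Compton linear attenuation stays below the total attenuation", {
  for (E in c(40, 60, 80, 100, 140)) {
    expect_lt(compton_linear_attenuation("water", E),
              linear_attenuation("water", E))
    expect_gt(compton_linear_attenuation("water", E), 0)
  }
})
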