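test_that("frame write/read roundtrips readings and metadata exactly", {
  set.seed(11)
  r <- matrix(runif(8 * 20, 0, 1e6), 8, 20)
  f <- detector_frame(r, kvp = 120, tube_current = 100, exposure_s = 3,
                      phantom_present = TRUE, blocker_present = TRUE,
                      seed = 77L)
  path <- withr::local_tempfile(fileext = ".ctraw")
  write_frame(f, path)
  g <- read_frame(path)
  expect_equal(g$readings, r, tolerance = 1e-6)  # float32 payload
  expect_identical(g$meta[c("phantom_present", "blocker_present",
                            "calibrated")],
                   f$meta[c("phantom_present", "blocker_present",
                            "calibrated")])
  expect_identical(g$meta$seed, 77L)
  expect_equal(g$meta$kvp, 120)
})

test_that("a 64 x 912 float frame is exactly header plus payload bytes", {
  f <- detector_frame(matrix(0, 64, 912))
  path <- withr::local_tempfile(fileext = ".ctraw")
  write_frame(f, path)
  expect_equal(file.info(path)$size, 66 + 64 * 912 * 4)
})

test_that("bad magic and truncated payloads are format errors", {
  path <- withr::local_tempfile(fileext = ".ctraw")
  writeBin(charToRaw("NOTAFRAME"), path)
  expect_error(read_frame(path), "magic")
  f <- detector_frame(matrix(1, 4, 6))
  write_frame(f, path)
  sz <- file.info(path)$size
  trunc <- readBin(path, "raw", sz - 10)
  writeBin(trunc, path)
  expect_error(read_frame(path), "expected.*bytes")
})

test_that("uint16 compression roundtrips within half a quantisation step", {
  set.seed(5)
  r <- matrix(runif(16 * 30, 0, 5e5), 16, 30)
  f <- detector_frame(r)
  path <- withr::local_tempfile(fileext = ".ctraw")
  write_frame(f, path, compression = "uint16")
  g <- read_frame(path)
  step <- (max(r) - min(r)) / 65535
  expect_lt(max(abs(g$readings - r)), step / 2 + 1e-9)
})

test_that("calibrate/decalibrate roundtrip and decalibration is linear", {
  geom <- scanner_geometry(n_rows = 8, n_channels_active = 40,
                           n_channels_reference = 4)
  tab <- make_calibration_table(geom, seed = 3)
  set.seed(9)
  r <- matrix(runif(8 * 44, 1, 100), 8, 44)
  f <- detector_frame(r)
  back <- decalibrate(calibrate(f, tab), tab)
  expect_equal(back$readings, r, tolerance = 1e-12)
  expect_false(back$meta$calibrated)
  # linearity: decalibrate(a x) = a decalibrate(x)
  fa <- calibrate(detector_frame(3.5 * r), tab)
  expect_equal(decalibrate(fa, tab)$readings,
               3.5 * decalibrate(calibrate(f, tab), tab)$readings,
               tolerance = 1e-12)
})

test_that("calibration misuse is caught", {
  geom <- scanner_geometry(n_rows = 4, n_channels_active = 10,
                           n_channels_reference = 2)
  tab <- identity_calibration(geom)
  f <- detector_frame(matrix(1, 4, 12))
  expect_error(decalibrate(f, tab), "calibrated flag")
  expect_error(calibrate(calibrate(f, tab), tab), "calibrated flag")
  expect_error(calibrate(detector_frame(matrix(1, 3, 12)), tab), "shapes")
  expect_error(calibration_table(matrix(c(1, -1), 1, 2)), "positive")
})

test_that("calibration tables roundtrip through their own container", {
  geom <- scanner_geometry(n_rows = 6, n_channels_active = 20,
                           n_channels_reference = 2)
  tab <- make_calibration_table(geom, seed = 21, compression = "uint16")
  path <- withr::local_tempfile(fileext = ".ctcal")
  write_calibration(tab, path)
  got <- read_calibration(path)
  expect_equal(got$gains, tab$gains, tolerance = 1e-6)
  expect_identical(got$compression, "uint16")
  # a frame file is not a calibration file
  fpath <- withr::local_tempfile(fileext = ".ctraw")
  write_frame(detector_frame(matrix(0, 2, 2)), fpath)
  expect_error(read_calibration(fpath), "magic")
})
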