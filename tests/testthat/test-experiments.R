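test_that("an empty design yields an empty passing report", {
  d <- study_design("empty")
  rep <- run_design(d, withr::local_tempdir())
  expect_true(rep$pass)
  expect_equal(nrow(rep$verdicts), 0)
})

test_that("shipped design files parse with their assertions", {
  for (f in list.files(system.file("designs", package = "ctscatter"),
                       full.names = TRUE)) {
    d <- read_design(f)
    expect_s3_class(d, "study_design")
    expect_true(all(d$assertions %in% names(design_assertions())))
    expect_gt(nrow(d$runs), 0)
  }
  expect_error(study_design("x", "water215", 120,
                            assertions = "no_such_check"),
               "unknown assertion")
})

test_that("a reduced smoke design runs end to end and passes its assertions", {
  d <- study_design("mini", phantoms = "water215", kvps = c(80, 140),
                    ma = 100, assertions = c("scatter_two_peaks",
                                             "row_mirror_symmetry"),
                    n_photons = 2e5, seed = 3)
  td <- withr::local_tempdir()
  rep <- run_design(d, td)
  expect_s3_class(rep, "design_report")
  expect_equal(nrow(rep$verdicts), 2)
  expect_true(rep$pass)
  expect_true(file.exists(file.path(td, "report.tsv")))
  # determinism of the verdict report
  rep2 <- run_design(d, withr::local_tempdir())
  expect_equal(rep2$verdicts$margin, rep$verdicts$margin)
})
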