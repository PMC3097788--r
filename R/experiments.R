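#' Study design
#'
#' A named, seeded experiment definition binding simulator acquisitions
#' to pipeline runs and property assertions.  A design expands to one
#' acquisition pair per (phantom, kVp, offset) combination; assertions
#' are named checks from the registry in [design_assertions()].
#'
#' @param name design name
#' @param phantoms standard phantom names (see [standard_phantom()])
#' @param kvps tube voltages
#' @param ma tube currents, one per phantom (recycled)
#' @param offsets signed axial offsets, mm
#' @param assertions character vector of assertion names
#' @param n_photons Monte Carlo budget per acquisition
#' @param exposure_s exposure time, s
#' @param seed base seed
#' @export
study_design <- function(name, phantoms = character(0), kvps = numeric(0),
                         ma = 100, offsets = 0,
                         assertions = character(0), n_photons = 1e6,
                         exposure_s = 3, seed = 1) {
  ma <- rep_len(ma, max(length(phantoms), 1L))
  runs <- NULL
  for (i in seq_along(phantoms))
    runs <- rbind(runs, expand.grid(phantom = phantoms[i], kvp = kvps,
                                    offset = offsets, ma = ma[i],
                                    stringsAsFactors = FALSE))
  unknown <- setdiff(assertions, names(design_assertions()))
  if (length(unknown))
    stop("unknown assertion(s): ", paste(unknown, collapse = ", "))
  structure(list(name = name, runs = runs, assertions = assertions,
                 n_photons = n_photons, exposure_s = exposure_s,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Read a study design from a configuration file
#'
#' Keys: `name`, `phantoms`, `kvps`, `ma` (one per phantom), `offsets`,
#' `exposure_s`, `n_photons`, `seed`, and one `assert` line per
#' assertion.  Unknown keys are an error.
#'
#' @param path design file (see the shipped files under `inst/designs/`)
#' @export
read_design <- function(path) {
  cfg <- .parse_config(path)
  .cfg_check_keys(cfg, c("name", "phantoms", "kvps", "ma", "offsets",
                         "exposure_s", "n_photons", "seed", "assert"),
                  "design")
  asserts <- if ("assert" %in% names(cfg))
    unlist(cfg[["assert"]]) else character(0)
  study_design(
    name = .cfg_get(cfg, "name", tools::file_path_sans_ext(basename(path))),
    phantoms = .cfg_get(cfg, "phantoms", character(0)),
    kvps = .cfg_get(cfg, "kvps", numeric(0)),
    ma = .cfg_get(cfg, "ma", 100),
    offsets = .cfg_get(cfg, "offsets", 0),
    assertions = asserts,
    n_photons = .cfg_get(cfg, "n_photons", 1e6),
    exposure_s = .cfg_get(cfg, "exposure_s", 3),
    seed = .cfg_get(cfg, "seed", 1))
}

#' Assertion registry for study designs
#'
#' Each assertion receives the trend/integrated tables from [run_study()]
#' and returns `list(pass, margin, detail)`; `margin` is the measured
#' distance to the pass/fail boundary (positive = pass).
#'
#' * `integrated_spr_decreasing_kvp`: integrated SPR of the central row
#'   strictly decreases with kVp for every phantom.
#' * `integrated_spr_increasing_offset`: integrated SPR strictly
#'   increases with signed offset toward the detector (air-gap effect).
#' * `scatter_two_peaks`: the central-channel scatter lies below the
#'   profile maximum (two-peaked profile of a centred cylinder).
#' * `row_mirror_symmetry`: integrated SPR is mirror-symmetric across
#'   rows about the central row pair (relative tolerance 0.1, covering
#'   Monte Carlo error).
#' * `phantom_size_ordering`: at equal kVp the 300 mm phantom's
#'   integrated SPR exceeds the 215 mm phantom's.
#' @export
design_assertions <- function() list(
  integrated_spr_decreasing_kvp = function(res) {
    margins <- c()
    for (ph in unique(res$trend$phantom)) {
      tr <- res$trend[res$trend$phantom == ph & res$trend$offset_mm == 0, ]
      tr <- tr[order(tr$kvp), ]
      if (nrow(tr) >= 2) margins <- c(margins, -diff(tr$integrated_spr))
    }
    list(pass = length(margins) > 0 && all(margins > 0),
         margin = if (length(margins)) min(margins) else NA_real_,
         detail = "min consecutive drop of integrated SPR over kVp")
  },
  integrated_spr_increasing_offset = function(res) {
    tr <- res$trend[order(res$trend$offset_mm), ]
    d <- diff(tr$integrated_spr)
    list(pass = length(d) > 0 && all(d > 0),
         margin = if (length(d)) min(d) else NA_real_,
         detail = "min rise of integrated SPR per offset step toward detector")
  },
  scatter_two_peaks = function(res) {
    margins <- vapply(unique(res$profiles$id), function(id) {
      p <- res$profiles[res$profiles$id == id, ]
      centre <- mean(p$scatter[abs(p$channel - (max(p$channel) / 2)) < 1])
      (max(p$scatter) - centre) / max(p$scatter)
    }, numeric(1))
    list(pass = all(margins > 0), margin = min(margins),
         detail = "relative depth of the central scatter dip")
  },
  row_mirror_symmetry = function(res, tol = 0.1) {
    rows <- grep("^row", names(res$integrated))
    margins <- apply(res$integrated[, rows, drop = FALSE], 1, function(v) {
      tol - max(abs(v - rev(v)) / max(v))
    })
    list(pass = all(margins > 0), margin = min(margins),
         detail = "0.1 minus max relative row-mirror asymmetry")
  },
  phantom_size_ordering = function(res) {
    tr <- res$trend[res$trend$offset_mm == 0, ]
    margins <- c()
    for (k in unique(tr$kvp)) {
      big <- tr$integrated_spr[tr$kvp == k & tr$phantom == "poly300"]
      small <- tr$integrated_spr[tr$kvp == k & tr$phantom == "water215"]
      if (length(big) && length(small)) margins <- c(margins, big - small)
    }
    list(pass = length(margins) > 0 && all(margins > 0),
         margin = if (length(margins)) min(margins) else NA_real_,
         detail = "integrated SPR excess of the 300 mm over the 215 mm phantom")
  })

#' Run a study design
#'
#' Generates the design's fixtures, runs the measurement pipeline on
#' every pair, evaluates each assertion, and writes a pass/fail report
#' with measured margins.  Deterministic given the design's seed.
#'
#' @param design a [study_design()] or path to a design file
#' @param out_dir output directory for fixtures, tables and
#'   `report.tsv`
#' @param row 1-based detector row used by the assertions (default 32)
#' @return object of class `design_report`: data frame `verdicts`
#'   (assertion, pass, margin, detail), logical `pass`, and the pipeline
#'   results; an empty design yields an empty, passing report
#' @export
run_design <- function(design, out_dir, row = 32) {
  if (is.character(design)) design <- read_design(design)
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verdicts <- data.frame(assertion = character(0), pass = logical(0),
                         margin = numeric(0), detail = character(0))
  res <- NULL
  if (!is.null(design$runs) && nrow(design$runs) > 0) {
    geom <- scanner_geometry()
    blocker <- default_blocker_array(geom)
    manifest <- NULL
    for (i in seq_len(nrow(design$runs))) {
      r <- design$runs[i, ]
      id <- sprintf("%s_%s_%03dkvp_off%+04d", design$name, r$phantom,
                    r$kvp, r$offset)
      setup <- acquisition_setup(
        geom, standard_phantom(r$phantom, axial_offset = r$offset),
        blocker, xray_spectrum(r$kvp), tube_current = r$ma,
        exposure_s = design$exposure_s, n_photons = design$n_photons,
        seed = design$seed)
      render_acquisition_pair(setup, NULL, out_dir, id)
      manifest <- rbind(manifest, data.frame(
        id = id, phantom = r$phantom, kvp = r$kvp, ma = r$ma,
        offset_mm = r$offset, seed = design$seed,
        with_file = paste0(id, "_with.ctraw"),
        without_file = paste0(id, "_without.ctraw"),
        truth_file = paste0(id, "_truth.txt")))
    }
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res <- run_study(file.path(out_dir, "manifest.tsv"), out_dir, row = row)
    registry <- design_assertions()
    for (a in design$assertions) {
      v <- registry[[a]](res)
      verdicts <- rbind(verdicts, data.frame(
        assertion = a, pass = v$pass, margin = v$margin, detail = v$detail))
    }
  }
  write.table(verdicts, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  structure(list(name = design$name, verdicts = verdicts,
                 pass = all(verdicts$pass), results = res),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s: %s (%d assertion(s))\n", x$name,
              if (x$pass) "PASS" else "FAIL", nrow(x$verdicts)))
  if (nrow(x$verdicts))
    for (i in seq_len(nrow(x$verdicts)))
      cat(sprintf("  %-34s %-5s margin %.4g\n", x$verdicts$assertion[i],
                  ifelse(x$verdicts$pass[i], "pass", "FAIL"),
                  x$verdicts$margin[i]))
  invisible(x)
}
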