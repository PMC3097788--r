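#' Run the full blocker-array SPR measurement on an acquisition pair
#'
#' The measurement algorithm end to end: decalibrate both frames (when a
#' calibration table is supplied), compensate the blocker's own scatter
#' using the no-phantom exposure, average the shadow-core readings of
#' each bar into per-row scatter samples, interpolate scatter to every
#' channel, fill the shadowed channels of the total profile from the
#' open channels, deduce primary as total minus scatter, and form
#' per-channel SPR and per-row integrated SPR.  Rows are processed
#' independently.
#'
#' @param with_phantom,without_phantom [detector_frame()]s of the pair
#'   (paths to `.ctraw` files are also accepted)
#' @param geom the [scanner_geometry()] of the acquisition
#' @param blocker the [blocker_array()] used, or a ready-made
#'   [project_shadow()] mask via `mask`
#' @param mask optional precomputed shadow mask (overrides `blocker`)
#' @param calibration optional [calibration_table()]; required when the
#'   frames are flagged calibrated
#' @param penumbra_margin guard channels around each shadow core
#' @param primary_floor SPR validity floor, see [spr_profile()]
#' @return an object of class `spr_measurement` with matrices `scatter`,
#'   `total`, `primary`, `spr` (NA = masked) of size rows x channels,
#'   the per-row `integrated` SPR vector, the shadow `mask`, the bar
#'   `samples`, and acquisition `meta`
#' @export
measure_spr <- function(with_phantom, without_phantom, geom,
                        blocker = NULL, mask = NULL, calibration = NULL,
                        penumbra_margin = 2, primary_floor = 1e-3) {
  if (is.character(with_phantom)) with_phantom <- read_frame(with_phantom)
  if (is.character(without_phantom))
    without_phantom <- read_frame(without_phantom)
  stopifnot(inherits(geom, "scanner_geometry"))
  if (is.null(mask)) {
    if (is.null(blocker)) stop("either a blocker or a shadow mask is required")
    mask <- project_shadow(geom, blocker, penumbra_margin)
  }
  if (with_phantom$meta$calibrated || without_phantom$meta$calibrated) {
    if (is.null(calibration))
      stop("frames are calibrated; a calibration table is required")
    if (with_phantom$meta$calibrated)
      with_phantom <- decalibrate(with_phantom, calibration)
    if (without_phantom$meta$calibrated)
      without_phantom <- decalibrate(without_phantom, calibration)
  }
  comp <- compensate_blocker_scatter(with_phantom, without_phantom, mask)
  sam <- sample_shadow_scatter(comp, mask)
  nr <- nrow(comp$readings); nch <- ncol(comp$readings)
  scatter <- t(vapply(seq_len(nr), function(r)
    interpolate_scatter(sam$positions, sam$samples[r, ], nch),
    numeric(nch)))
  total <- total_profile(with_phantom, mask)
  primary <- primary_profile(total, scatter)
  spr <- t(vapply(seq_len(nr), function(r)
    spr_profile(scatter[r, ], primary[r, ], primary_floor), numeric(nch)))
  structure(list(scatter = scatter, total = total, primary = primary,
                 spr = spr, integrated = integrated_spr(spr),
                 samples = sam, mask = mask, meta = with_phantom$meta,
                 primary_floor = primary_floor),
            class = "spr_measurement")
}

#' @export
print.spr_measurement <- function(x, ...) {
  nr <- nrow(x$spr)
  central <- nr %/% 2            # row 32 for 64 rows, 1-based label
  cat(sprintf("<spr_measurement> %d rows x %d channels, %g kVp, %g mA\n",
              nr, ncol(x$spr), x$meta$kvp, x$meta$tube_current))
  cat(sprintf("  integrated SPR: row %d = %.3f; range over rows %.3f-%.3f\n",
              central, x$integrated[central],
              min(x$integrated), max(x$integrated)))
  invisible(x)
}

#' @export
summary.spr_measurement <- function(object, row = NULL, ...) {
  nr <- nrow(object$spr)
  if (is.null(row)) row <- nr %/% 2
  s <- object$spr[row, ]
  cat(sprintf("SPR measurement summary (row %d of %d, 1-based)\n", row, nr))
  cat(sprintf("  channels masked: %d of %d\n", sum(is.na(s)), length(s)))
  cat(sprintf("  SPR: median %.4f, max %.4f at channel %d (0-based)\n",
              stats::median(s, na.rm = TRUE), max(s, na.rm = TRUE),
              which.max(s) - 1L))
  cat(sprintf("  integrated SPR this row: %.3f\n", object$integrated[row]))
  cat(sprintf("  integrated SPR all rows: min %.3f / median %.3f / max %.3f\n",
              min(object$integrated), stats::median(object$integrated),
              max(object$integrated)))
  invisible(object)
}

#' Plot measured profiles for one detector row
#'
#' `what = "profiles"` draws total, scatter and primary against channel;
#' `what = "spr"` draws the per-channel SPR.  Rows are labelled 1-based,
#' so the central row of the 64-row detector is row 32.
#'
#' @param x an `spr_measurement`
#' @param row 1-based detector row (default: central row)
#' @param what `"profiles"` or `"spr"`
#' @param ... passed to [graphics::matplot()] / `plot()`
#' @export
plot.spr_measurement <- function(x, row = NULL, what = c("profiles", "spr"),
                                 ...) {
  what <- match.arg(what)
  nr <- nrow(x$spr)
  if (is.null(row)) row <- nr %/% 2
  ch <- seq_len(ncol(x$spr)) - 1L
  if (what == "profiles") {
    matplot(ch, cbind(x$total[row, ], x$scatter[row, ], x$primary[row, ]),
            type = "l", lty = 1, col = c("black", "red", "blue"),
            xlab = "channel", ylab = "detector reading",
            main = sprintf("row %d profiles", row), ...)
    legend("topright", c("total", "scatter", "primary"),
           col = c("black", "red", "blue"), lty = 1, bty = "n")
  } else {
    plot(ch, x$spr[row, ], type = "l", xlab = "channel", ylab = "SPR",
         main = sprintf("row %d SPR (integrated %.2f)", row,
                        x$integrated[row]), ...)
  }
  invisible(x)
}

#' Analyse every acquisition pair of a manifest
#'
#' Runs the full measurement on each pair listed in a manifest written by
#' [make_study_fixtures()] and collects result tables: per-channel
#' profiles for a chosen row, integrated SPR for all rows, and the
#' off-centring trend.  Tables are written as tab-delimited text when
#' `out_dir` is given.
#'
#' @param manifest manifest data frame or path to `manifest.tsv`; file
#'   paths inside are resolved relative to the manifest's directory
#' @param out_dir optional output directory for the delimited tables and
#'   run log
#' @param row 1-based detector row for the profile table (default 32)
#' @param calibration optional [calibration_table()] when the frames are
#'   calibrated
#' @param geom,blocker acquisition geometry and blocker; defaults are the
#'   study's scanner and bar layout
#' @return list with `integrated` (one line per pair, integrated SPR for
#'   every row), `profiles` (long table for the chosen row), `trend`
#'   (integrated SPR of the chosen row per pair) and `measurements` (the
#'   `spr_measurement` objects, named by pair id)
#' @export
run_study <- function(manifest, out_dir = NULL, row = 32,
                      calibration = NULL,
                      geom = scanner_geometry(),
                      blocker = default_blocker_array(geom)) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  need <- c("id", "with_file", "without_file")
  if (!all(need %in% names(manifest)))
    stop("manifest lacks required columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  mask <- project_shadow(geom, blocker)
  log_lines <- character(0)
  measurements <- list(); integrated <- NULL; profiles <- NULL; trend <- NULL
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    wf <- file.path(base_dir, mrow$with_file)
    wof <- file.path(base_dir, mrow$without_file)
    if (!file.exists(wf) || !file.exists(wof))
      stop("manifest entry '", mrow$id, "': missing pair member ",
           if (!file.exists(wf)) wf else wof)
    m <- measure_spr(wf, wof, geom, mask = mask, calibration = calibration)
    measurements[[mrow$id]] <- m
    integrated <- rbind(integrated, data.frame(
      mrow[intersect(c("id", "phantom", "kvp", "ma", "offset_mm"),
                     names(mrow))],
      t(setNames(m$integrated, paste0("row", seq_along(m$integrated))))))
    profiles <- rbind(profiles, data.frame(
      id = mrow$id, channel = seq_len(ncol(m$spr)) - 1L,
      scatter = m$scatter[row, ], total = m$total[row, ],
      primary = m$primary[row, ], spr = m$spr[row, ]))
    trend <- rbind(trend, data.frame(
      mrow[intersect(c("id", "phantom", "kvp", "offset_mm"), names(mrow))],
      integrated_spr = m$integrated[row]))
    log_lines <- c(log_lines, sprintf(
      "%s: integrated SPR row %d = %.4f", mrow$id, row, m$integrated[row]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(integrated, file.path(out_dir, "integrated_spr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(profiles, file.path(out_dir,
                                    sprintf("profiles_row%02d.tsv", row)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(trend, file.path(out_dir, "trend.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(integrated = integrated, profiles = profiles,
                 trend = trend, measurements = measurements))
}
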