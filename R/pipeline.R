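#' Compensate the blocker's own scatter
#'
#' The method irradiates twice - once without and once with the phantom,
#' blocker in place both times - so that scatter generated by the lead
#' array itself (recorded in the no-phantom exposure) can be removed from
#' the shadow readings.  The no-phantom frame is subtracted elementwise
#' on blocker-affected (shadow-core and penumbra) channels only and the
#' result clamped at zero; open channels, which carry the full primary
#' flux in the no-phantom exposure, are left untouched.
#'
#' @param with_phantom,without_phantom decalibrated [detector_frame()]s
#'   with the blocker present; phantom flag must be TRUE/FALSE
#'   respectively
#' @param mask the [project_shadow()] mask of the acquisition
#' @return the compensated with-phantom frame; `meta$compensated` is set
#' @export
compensate_blocker_scatter <- function(with_phantom, without_phantom, mask) {
  stopifnot(inherits(with_phantom, "detector_frame"),
            inherits(without_phantom, "detector_frame"),
            inherits(mask, "shadow_mask"))
  if (!identical(dim(with_phantom$readings), dim(without_phantom$readings)))
    stop("frame shapes differ")
  if (with_phantom$meta$calibrated || without_phantom$meta$calibrated)
    stop("both frames must be decalibrated first")
  if (!with_phantom$meta$phantom_present || without_phantom$meta$phantom_present)
    stop("expected phantom flags TRUE (with) and FALSE (without)")
  if (!with_phantom$meta$blocker_present || !without_phantom$meta$blocker_present)
    stop("both frames must have the blocker present")
  shadow <- mask$labels != "open"
  out <- with_phantom
  out$readings[, shadow] <- pmax(
    with_phantom$readings[, shadow] - without_phantom$readings[, shadow], 0)
  out$meta$compensated <- TRUE
  out
}

#' Sample scatter in the bar shadows
#'
#' One sample per bar per row: the mean reading over that bar's
#' shadow-core channels (penumbra excluded), positioned at the shadow
#' interval's centre channel.
#'
#' @param frame a decalibrated, blocker-compensated [detector_frame()]
#' @param mask the acquisition's [project_shadow()] mask
#' @return list with `positions` (continuous channel positions, one per
#'   bar) and `samples` (`n_rows x n_bars` matrix)
#' @export
sample_shadow_scatter <- function(frame, mask) {
  stopifnot(inherits(frame, "detector_frame"), inherits(mask, "shadow_mask"))
  if (frame$meta$calibrated) stop("frame must be decalibrated first")
  if (!isTRUE(frame$meta$compensated))
    stop("frame must be blocker-compensated first (see compensate_blocker_scatter)")
  bars <- mask$bars
  if (any(is.na(bars$core_first)))
    stop("bar(s) ", paste(bars$bar[is.na(bars$core_first)], collapse = ", "),
         " have no shadow-core channels after the penumbra margin")
  samples <- vapply(seq_len(nrow(bars)), function(b) {
    cols <- (bars$core_first[b]:bars$core_last[b]) + 1L
    rowMeans(frame$readings[, cols, drop = FALSE])
  }, numeric(nrow(frame$readings)))
  list(positions = bars$center_channel,
       samples = matrix(samples, nrow = nrow(frame$readings)))
}

#' Interpolate a scatter profile to every channel
#'
#' Monotone-preserving piecewise cubic (Fritsch-Carlson) through the bar
#' samples, evaluated at all channels; constant extrapolation beyond the
#' outermost samples; negative values clamped at zero.  Monotone cubics
#' reproduce linear data exactly and cannot overshoot into negative
#' scatter between samples.
#'
#' @param positions strictly increasing sample positions (continuous
#'   channel coordinates)
#' @param values scatter samples at `positions`
#' @param n_channels number of channels to evaluate at (0-based grid
#'   `0:(n_channels-1)`)
#' @return numeric vector of length `n_channels`
#' @export
interpolate_scatter <- function(positions, values, n_channels) {
  if (length(positions) < 2) stop("need at least 2 scatter samples")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  stopifnot(length(positions) == length(values))
  f <- splinefun(positions, values, method = "monoH.FC")
  x <- pmin(pmax(0:(n_channels - 1), min(positions)), max(positions))
  pmax(f(x), 0)
}

#' Total-radiation profile with shadows filled in
#'
#' Open channels record total (primary plus scatter) radiation directly;
#' shadow and penumbra channels are filled by the same
#' monotone-cubic interpolation applied to the open-channel readings.
#'
#' @param frame a decalibrated [detector_frame()]
#' @param mask the acquisition's [project_shadow()] mask; NULL means no
#'   blocker (every channel open)
#' @return `n_rows x n_channels` matrix
#' @export
total_profile <- function(frame, mask = NULL) {
  stopifnot(inherits(frame, "detector_frame"))
  if (frame$meta$calibrated) stop("frame must be decalibrated first")
  if (is.null(mask)) return(frame$readings)
  open <- which(mask$labels == "open") - 1L
  if (length(open) == ncol(frame$readings)) return(frame$readings)
  out <- frame$readings
  fillme <- which(mask$labels != "open")
  for (r in seq_len(nrow(out))) {
    f <- splinefun(open, frame$readings[r, open + 1L], method = "monoH.FC")
    x <- pmin(pmax(fillme - 1L, min(open)), max(open))
    out[r, fillme] <- pmax(f(x), 0)
  }
  out
}

#' Primary radiation by subtraction
#'
#' Elementwise total minus scatter, clamped at zero.
#'
#' @param total,scatter equal-length vectors (or equal-shape matrices)
#' @export
primary_profile <- function(total, scatter) {
  if (length(total) != length(scatter))
    stop("total and scatter lengths differ")
  pmax(total - scatter, 0)
}

#' Scatter-to-primary ratio profile
#'
#' `SPR = scatter / primary` wherever the primary exceeds
#' `primary_floor` times its maximum; elsewhere the channel is masked
#' (NA).  The floor keeps near-zero primaries (edge and reference
#' channels in off-centred acquisitions) from blowing the ratio up.
#'
#' @param scatter,primary equal-length nonnegative vectors
#' @param primary_floor validity floor as a fraction of `max(primary)`,
#'   in (0, 1); default 1e-3
#' @return numeric vector with NA at masked channels
#' @export
spr_profile <- function(scatter, primary, primary_floor = 1e-3) {
  if (length(scatter) != length(primary))
    stop("scatter and primary lengths differ")
  if (primary_floor <= 0 || primary_floor >= 1)
    stop("primary_floor must be in (0, 1)")
  valid <- primary > primary_floor * max(primary)
  if (!any(valid)) stop("all channels masked: primary is degenerate")
  out <- rep(NA_real_, length(primary))
  out[valid] <- scatter[valid] / primary[valid]
  out
}

#' Integrated SPR of a row
#'
#' The sum of the SPR over all detectors in a row; masked channels
#' contribute zero.
#'
#' @param profile an SPR vector from [spr_profile()] (NA = masked), or a
#'   matrix of per-row profiles
#' @return scalar, or per-row vector for a matrix input
#' @export
integrated_spr <- function(profile) {
  if (is.matrix(profile)) return(apply(profile, 1, integrated_spr))
  if (all(is.na(profile))) return(0)
  sum(profile, na.rm = TRUE)
}
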