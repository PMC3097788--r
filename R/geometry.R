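#' Scanner geometry
#'
#' Fan/cone geometry of the 64-slice scanner.  Defaults are the studied
#' system: source-to-isocentre 540 mm, source-to-detector 950 mm, the
#' blocker plane 160 mm below the source, 64 detector rows of 912
#' channels (888 active patient elements plus 24 reference elements), a
#' 56 degree fan angle and 0.625 mm row pitch at isocentre.
#'
#' Channels and rows are indexed 0-based internally; user-facing reports
#' label rows 1-64 so that "row 32" is the central row.  Channel angles
#' are sampled uniformly in angle with the fan centre falling between the
#' two middle channels.
#'
#' @param source_to_iso,source_to_detector,blocker_plane distances, mm
#' @param n_rows,n_channels_active,n_channels_reference counts
#' @param fan_angle full fan angle, degrees
#' @param row_pitch_at_iso detector row pitch at isocentre, mm
#' @return object of class `scanner_geometry`
#' @export
scanner_geometry <- function(source_to_iso = 540,
                             source_to_detector = 950,
                             blocker_plane = 160,
                             n_rows = 64,
                             n_channels_active = 888,
                             n_channels_reference = 24,
                             fan_angle = 56,
                             row_pitch_at_iso = 0.625) {
  n_channels_total <- n_channels_active + n_channels_reference
  if (!(blocker_plane > 0 && blocker_plane < source_to_iso &&
        source_to_iso < source_to_detector))
    stop("need 0 < blocker_plane < source_to_iso < source_to_detector")
  if (fan_angle <= 0) stop("fan_angle must be positive")
  counts <- c(n_rows, n_channels_active, n_channels_reference)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("row/channel counts must be positive integers")
  structure(list(
    source_to_iso = source_to_iso,
    source_to_detector = source_to_detector,
    blocker_plane = blocker_plane,
    n_rows = as.integer(n_rows),
    n_channels_total = as.integer(n_channels_total),
    n_channels_active = as.integer(n_channels_active),
    n_channels_reference = as.integer(n_channels_reference),
    fan_angle = fan_angle,
    row_pitch_at_iso = row_pitch_at_iso
  ), class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<scanner_geometry> SID %g mm, SDD %g mm, blocker plane %g mm\n",
    "  %d rows x %d channels (%d active + %d reference), fan %g deg,\n",
    "  row pitch %g mm at iso (%d detector elements)\n"),
    x$source_to_iso, x$source_to_detector, x$blocker_plane,
    x$n_rows, x$n_channels_total, x$n_channels_active,
    x$n_channels_reference, x$fan_angle, x$row_pitch_at_iso,
    x$n_rows * x$n_channels_total))
  invisible(x)
}

# angular pitch per channel, degrees
channel_pitch <- function(geom) geom$fan_angle / geom$n_channels_total

#' Fan angle of a detector channel
#'
#' Uniform angular sampling of the fan over all channels, antisymmetric
#' about the fan centre, which falls between the two middle channels
#' (channels 455 and 456 for the default 912-channel row, 0-based).
#' Fractional channel positions are allowed (e.g. 455.5 is the centre).
#'
#' @param geom a [scanner_geometry()]
#' @param channel_index 0-based channel index (vectorised; may be
#'   fractional)
#' @return angle in degrees, negative on the low-channel side
#' @export
channel_fan_angle <- function(geom, channel_index) {
  stopifnot(inherits(geom, "scanner_geometry"))
  if (any(channel_index < 0) || any(channel_index >= geom$n_channels_total))
    stop("channel_index out of range [0, ", geom$n_channels_total - 1, "]")
  (channel_index - (geom$n_channels_total - 1) / 2) * channel_pitch(geom)
}

#' Cylindrical phantom
#'
#' A cylinder with its axis along the detector rows (the z axis), filled
#' with `fill_material`, optionally inside a wall annulus, and optionally
#' off-centred along the source-detector axis (positive toward the
#' detector).
#'
#' @param fill_diameter inner (fill) diameter, mm
#' @param fill_material material name, see [ct_material()]
#' @param wall_thickness wall thickness, mm (0 for a solid cylinder)
#' @param wall_material wall material name, or NULL when no wall
#' @param axial_offset signed offset along the source-detector axis, mm;
#'   positive moves the phantom toward the detector
#' @export
ct_phantom <- function(fill_diameter, fill_material,
                       wall_thickness = 0, wall_material = NULL,
                       axial_offset = 0) {
  if (fill_diameter <= 0) stop("fill_diameter must be positive")
  if (wall_thickness < 0) stop("wall_thickness must be nonnegative")
  if (wall_thickness > 0 && is.null(wall_material))
    stop("wall_material required when wall_thickness > 0")
  structure(list(
    fill_diameter = fill_diameter,
    fill_material = fill_material,
    wall_thickness = wall_thickness,
    wall_material = if (wall_thickness > 0) wall_material else NULL,
    axial_offset = axial_offset
  ), class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  wall <- if (x$wall_thickness > 0)
    sprintf(" + %g mm %s wall", x$wall_thickness, x$wall_material) else ""
  cat(sprintf("<ct_phantom> %g mm %s cylinder%s, axial offset %+g mm\n",
              x$fill_diameter, x$fill_material, wall, x$axial_offset))
  invisible(x)
}

#' Standard study phantoms
#'
#' `"water215"`: water cylinder of 215 mm internal diameter inside a 6 mm
#' Plexiglas (PMMA) wall.  `"poly300"`: solid 300 mm polypropylene
#' cylinder emulating an obese subject.
#'
#' @param which `"water215"` or `"poly300"`
#' @param axial_offset signed offset toward the detector, mm
#' @export
standard_phantom <- function(which = c("water215", "poly300"),
                             axial_offset = 0) {
  switch(match.arg(which),
    water215 = ct_phantom(215, "water", 6, "pmma", axial_offset),
    poly300  = ct_phantom(300, "polypropylene", axial_offset = axial_offset))
}

# outer radius including wall, mm
phantom_outer_radius <- function(phantom)
  phantom$fill_diameter / 2 + phantom$wall_thickness

# phantom must not reach source or detector
validate_phantom <- function(phantom, geom) {
  r <- phantom_outer_radius(phantom)
  lim <- min(geom$source_to_iso,
             geom$source_to_detector - geom$source_to_iso)
  if (abs(phantom$axial_offset) + r >= lim)
    stop("phantom (radius ", r, " mm, offset ", phantom$axial_offset,
         " mm) would intersect the source or detector")
  invisible(TRUE)
}

#' Path lengths of a channel's ray through a phantom
#'
#' Intersection of the source-to-channel ray with the fill cylinder and
#' (when present) the wall annulus.  For a ray passing at perpendicular
#' distance `d` from the cylinder axis the chord through a radius-`R`
#' cylinder is `2 sqrt(R^2 - d^2)` for `d < R` and 0 otherwise.
#'
#' @inheritParams channel_fan_angle
#' @param phantom a [ct_phantom()]
#' @return for a single channel, a named vector `c(fill =, wall =)` of
#'   path lengths in cm; for a vector of channels, a matrix with columns
#'   `fill` and `wall`
#' @export
chord_lengths <- function(geom, phantom, channel_index) {
  gamma <- channel_fan_angle(geom, channel_index) * pi / 180
  yc <- geom$source_to_iso + phantom$axial_offset
  d <- abs(yc * sin(gamma))
  chord <- function(R) ifelse(d < R, 2 * sqrt(pmax(R^2 - d^2, 0)), 0)
  r_fill <- phantom$fill_diameter / 2
  fill <- chord(r_fill)
  wall <- chord(phantom_outer_radius(phantom)) - fill
  if (length(channel_index) == 1) return(c(fill = fill / 10,
                                           wall = wall / 10))
  cbind(fill = fill / 10, wall = wall / 10)  # mm -> cm
}

#' Lead blocker-bar array
#'
#' A one-dimensional array of lead bars mounted in the blocker plane,
#' parallel to the detector rows, so a single shadow mask applies to all
#' 64 rows.  Bars must be pairwise non-overlapping.
#'
#' @param bar_centers signed lateral bar-centre positions in the blocker
#'   plane, mm
#' @param bar_width lateral bar width in the blocker plane, mm
#' @param bar_thickness bar thickness along the beam, mm
#' @param material bar material (lead)
#' @export
blocker_array <- function(bar_centers, bar_width = 2, bar_thickness = 3,
                          material = "lead") {
  if (bar_width <= 0 || bar_thickness <= 0)
    stop("bar dimensions must be positive")
  bar_centers <- sort(as.numeric(bar_centers))
  if (length(bar_centers) >= 2 && any(diff(bar_centers) < bar_width))
    stop("bars overlap: centres closer than bar_width")
  structure(list(
    n_bars = length(bar_centers),
    bar_width = bar_width,
    bar_thickness = bar_thickness,
    bar_centers = bar_centers,
    material = material
  ), class = "blocker_array")
}

#' @export
print.blocker_array <- function(x, ...) {
  cat(sprintf("<blocker_array> %d %s bars, %g mm wide, %g mm thick, centres %g..%g mm\n",
              x$n_bars, x$material, x$bar_width, x$bar_thickness,
              min(x$bar_centers), max(x$bar_centers)))
  invisible(x)
}

#' Default bar layout for a geometry
#'
#' `n_bars` bars evenly spaced across the central `coverage` fraction of
#' the fan width at the blocker plane, leaving open channels between
#' shadows for total-profile sampling.
#'
#' @param geom a [scanner_geometry()]
#' @param n_bars number of bars (default 20)
#' @param bar_width,bar_thickness bar dimensions, mm
#' @param coverage fraction of the fan half-width spanned by the array
#' @export
default_blocker_array <- function(geom, n_bars = 20, bar_width = 2,
                                  bar_thickness = 3, coverage = 0.9) {
  half <- geom$blocker_plane * tan(geom$fan_angle / 2 * pi / 180) * coverage
  blocker_array(seq(-half, half, length.out = n_bars),
                bar_width = bar_width, bar_thickness = bar_thickness)
}

# per-channel fraction of the channel's angular bin covered by bars,
# plus per-bar angular intervals (radians); used by the shadow mask and
# by the simulators
blocker_coverage <- function(geom, blocker) {
  p <- channel_pitch(geom) * pi / 180
  nch <- geom$n_channels_total
  lo_edge <- ((0:(nch - 1)) - nch / 2) * p        # channel bin left edges
  half_fan <- geom$fan_angle / 2 * pi / 180
  a_lo <- atan((blocker$bar_centers - blocker$bar_width / 2) /
                 geom$blocker_plane)
  a_hi <- atan((blocker$bar_centers + blocker$bar_width / 2) /
                 geom$blocker_plane)
  out_of_fan <- a_lo < -half_fan | a_hi > half_fan
  if (any(out_of_fan))
    stop("blocker bar(s) ", paste(which(out_of_fan), collapse = ", "),
         " extend outside the fan at the blocker plane")
  cov <- numeric(nch)
  per_bar <- vector("list", blocker$n_bars)
  for (b in seq_len(blocker$n_bars)) {
    ov <- pmax(0, pmin(lo_edge + p, a_hi[b]) - pmax(lo_edge, a_lo[b])) / p
    cov <- cov + ov
    per_bar[[b]] <- ov
  }
  cov <- pmin(cov, 1)
  # snap float fuzz so fully covered / fully open channels are exact,
  # consistent with the shadow-mask core criterion
  cov[cov > 1 - 1e-9] <- 1
  cov[cov < 1e-9] <- 0
  list(coverage = cov, per_bar = per_bar,
       bar_angles = cbind(lo = a_lo, hi = a_hi))
}

#' Project the blocker array onto the detector
#'
#' Bars are projected from the point source through the blocker plane to
#' the detector arc; each bar's shadow is its width magnified by
#' `source_to_detector / blocker_plane` (5.9375 for the default
#' geometry).  Channels fully covered by a bar form that bar's
#' `shadow_core`; partially covered boundary channels and
#' `penumbra_margin` further channels on each side are labelled
#' `penumbra_margin` and excluded from both scatter sampling and
#' total-profile sampling.  The source is modelled as a point, so the
#' margin guards interpolation against edge channels rather than
#' modelling focal-spot blur.
#'
#' @inheritParams channel_fan_angle
#' @param blocker a [blocker_array()]
#' @param penumbra_margin guard channels on each side of every shadow
#'   core (default 2)
#' @return object of class `shadow_mask`: per-channel labels in
#'   `{shadow_core, penumbra_margin, open}` plus per-bar interval records
#' @export
project_shadow <- function(geom, blocker, penumbra_margin = 2) {
  stopifnot(inherits(geom, "scanner_geometry"),
            inherits(blocker, "blocker_array"))
  bc <- blocker_coverage(geom, blocker)
  nch <- geom$n_channels_total
  eps <- 1e-9
  labels <- rep("open", nch)
  bars <- data.frame(bar = integer(0), core_first = integer(0),
                     core_last = integer(0), center_channel = numeric(0))
  p <- channel_pitch(geom) * pi / 180
  for (b in seq_len(blocker$n_bars)) {
    ov <- bc$per_bar[[b]]
    core <- which(ov >= 1 - eps) - 1L             # 0-based
    partial <- which(ov > eps & ov < 1 - eps) - 1L
    if (length(core) > 0 && any(diff(core) != 1L))
      stop("bar ", b, " produced a non-contiguous shadow core")
    centre_angle <- atan(blocker$bar_centers[b] / geom$blocker_plane)
    centre_channel <- centre_angle / p + nch / 2 - 0.5
    bars <- rbind(bars, data.frame(
      bar = b,
      core_first = if (length(core)) min(core) else NA_integer_,
      core_last = if (length(core)) max(core) else NA_integer_,
      center_channel = centre_channel))
    labels[core + 1L] <- "shadow_core"
    guard <- unique(c(partial,
                      if (length(core))
                        c(min(core) - seq_len(penumbra_margin),
                          max(core) + seq_len(penumbra_margin))))
    guard <- guard[guard >= 0 & guard < nch]
    guard <- setdiff(guard, core)
    labels[guard + 1L][labels[guard + 1L] == "open"] <- "penumbra_margin"
  }
  structure(list(labels = labels, bars = bars,
                 coverage = bc$coverage,
                 penumbra_margin = as.integer(penumbra_margin),
                 n_channels = nch,
                 magnification = geom$source_to_detector /
                   geom$blocker_plane),
            class = "shadow_mask")
}

#' @export
print.shadow_mask <- function(x, ...) {
  cat(sprintf("<shadow_mask> %d bars, magnification %.4f; %d shadow-core, %d penumbra, %d open channels\n",
              nrow(x$bars), x$magnification,
              sum(x$labels == "shadow_core"),
              sum(x$labels == "penumbra_margin"),
              sum(x$labels == "open")))
  invisible(x)
}
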