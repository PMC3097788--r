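# Plain-text key-value configuration files.
#
# Format: one `key = value` per line, '#' comments, blank lines ignored.
# Values are whitespace-separated tokens; numeric tokens are converted.
# Units are mm and degrees throughout.  Unknown keys are an error so a
# typo cannot silently fall back to a default.

.parse_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed configuration line (expected 'key = value'): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    toks <- strsplit(val, "[[:space:]]+")[[1]]
    nums <- suppressWarnings(as.numeric(toks))
    parsed <- if (!any(is.na(nums))) nums else toks
    out[[key]] <- if (key %in% names(out))
      c(out[[key]], list(parsed)) else list(parsed)
  }
  out
}

.cfg_get <- function(cfg, key, default) {
  if (!key %in% names(cfg)) return(default)
  v <- cfg[[key]]
  if (length(v) == 1) v[[1]] else v
}

.cfg_check_keys <- function(cfg, known, what) {
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown ", what, " configuration key(s): ",
         paste(unknown, collapse = ", "))
}

.geometry_keys <- c("source_to_iso_mm", "source_to_detector_mm",
                    "blocker_plane_mm", "n_rows", "n_channels_active",
                    "n_channels_reference", "fan_angle_deg",
                    "row_pitch_at_iso_mm")
.phantom_keys <- c("phantom", "phantom_offset_mm", "fill_diameter_mm",
                   "fill_material", "wall_thickness_mm", "wall_material")
.blocker_keys <- c("n_bars", "bar_width_mm", "bar_thickness_mm",
                   "blocker_coverage", "bar_centers_mm")
.acq_keys <- c("kvp", "ma", "exposure_s", "n_photons", "seed", "noise")

.geometry_from_cfg <- function(cfg) {
  g <- scanner_geometry()
  scanner_geometry(
    source_to_iso = .cfg_get(cfg, "source_to_iso_mm", g$source_to_iso),
    source_to_detector = .cfg_get(cfg, "source_to_detector_mm",
                                  g$source_to_detector),
    blocker_plane = .cfg_get(cfg, "blocker_plane_mm", g$blocker_plane),
    n_rows = .cfg_get(cfg, "n_rows", g$n_rows),
    n_channels_active = .cfg_get(cfg, "n_channels_active",
                                 g$n_channels_active),
    n_channels_reference = .cfg_get(cfg, "n_channels_reference",
                                    g$n_channels_reference),
    fan_angle = .cfg_get(cfg, "fan_angle_deg", g$fan_angle),
    row_pitch_at_iso = .cfg_get(cfg, "row_pitch_at_iso_mm",
                                g$row_pitch_at_iso))
}

.phantom_from_cfg <- function(cfg) {
  offset <- .cfg_get(cfg, "phantom_offset_mm", 0)
  std <- .cfg_get(cfg, "phantom", NULL)
  if (!is.null(std)) {
    if (identical(std, "none")) return(NULL)
    return(standard_phantom(std, axial_offset = offset))
  }
  dia <- .cfg_get(cfg, "fill_diameter_mm", NULL)
  if (is.null(dia)) return(NULL)
  ct_phantom(dia, .cfg_get(cfg, "fill_material", "water"),
             wall_thickness = .cfg_get(cfg, "wall_thickness_mm", 0),
             wall_material = .cfg_get(cfg, "wall_material", NULL),
             axial_offset = offset)
}

.blocker_from_cfg <- function(cfg, geom) {
  centers <- .cfg_get(cfg, "bar_centers_mm", NULL)
  width <- .cfg_get(cfg, "bar_width_mm", 2)
  thick <- .cfg_get(cfg, "bar_thickness_mm", 3)
  if (!is.null(centers))
    return(blocker_array(centers, width, thick))
  default_blocker_array(geom,
                        n_bars = .cfg_get(cfg, "n_bars", 20),
                        bar_width = width, bar_thickness = thick,
                        coverage = .cfg_get(cfg, "blocker_coverage", 0.9))
}

#' Read an experiment configuration file
#'
#' Plain-text `key = value` configuration describing geometry, phantom,
#' blocker and acquisition settings (units mm / degrees; see the shipped
#' example under `inst/extdata/example_config.cfg`).  Unknown keys are an
#' error.
#'
#' @param path configuration file
#' @return an [acquisition_setup()]
#' @export
read_acquisition_config <- function(path) {
  cfg <- .parse_config(path)
  .cfg_check_keys(cfg, c(.geometry_keys, .phantom_keys, .blocker_keys,
                         .acq_keys), "acquisition")
  geom <- .geometry_from_cfg(cfg)
  acquisition_setup(
    geometry = geom,
    phantom = .phantom_from_cfg(cfg),
    blocker = .blocker_from_cfg(cfg, geom),
    spectrum = xray_spectrum(.cfg_get(cfg, "kvp", 120)),
    tube_current = .cfg_get(cfg, "ma", 100),
    exposure_s = .cfg_get(cfg, "exposure_s", 3),
    n_photons = .cfg_get(cfg, "n_photons", 1e6),
    seed = .cfg_get(cfg, "seed", 1),
    noise = .cfg_get(cfg, "noise", "off"))
}
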