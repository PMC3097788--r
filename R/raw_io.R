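#' Raw detector frame
#'
#' One exposure's energy-integrated readings, a `n_rows x n_channels`
#' nonnegative matrix, plus acquisition metadata.
#'
#' @param readings numeric matrix (rows x channels), nonnegative
#' @param kvp,tube_current,exposure_s acquisition settings
#' @param phantom_present,blocker_present,calibrated logical flags
#' @param seed integer seed recorded with the frame
#' @export
detector_frame <- function(readings, kvp = NA_real_, tube_current = NA_real_,
                           exposure_s = NA_real_, phantom_present = FALSE,
                           blocker_present = FALSE, calibrated = FALSE,
                           seed = 0L) {
  readings <- as.matrix(readings)
  if (any(!is.finite(readings)) || any(readings < 0))
    stop("readings must be finite and nonnegative")
  structure(list(
    readings = readings,
    meta = list(kvp = kvp, tube_current = tube_current,
                exposure_s = exposure_s,
                phantom_present = isTRUE(phantom_present),
                blocker_present = isTRUE(blocker_present),
                calibrated = isTRUE(calibrated),
                seed = as.integer(seed))
  ), class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<detector_frame> %d x %d; %s kVp, %s mA, %s s; phantom=%s blocker=%s calibrated=%s\n",
    nrow(x$readings), ncol(x$readings), format(m$kvp), format(m$tube_current),
    format(m$exposure_s), m$phantom_present, m$blocker_present, m$calibrated))
  invisible(x)
}

.frame_magic <- "CTRAW001"
.cal_magic <- "CTCAL001"

# flags byte: bit0 phantom, bit1 blocker, bit2 calibrated
.pack_flags <- function(meta) {
  as.raw(1L * meta$phantom_present + 2L * meta$blocker_present +
           4L * meta$calibrated)
}

.write_container <- function(path, magic, payload_matrix, dtype,
                             scale = 1, offset = 0, kvp = NA_real_,
                             ma = NA_real_, exposure = NA_real_,
                             flags = as.raw(0), seed = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(magic), con)
  writeBin(as.integer(c(nrow(payload_matrix), ncol(payload_matrix))),
           con, size = 4, endian = "little")
  writeBin(as.raw(dtype), con)
  writeBin(as.double(c(scale, offset, kvp, ma, exposure)),
           con, size = 8, endian = "little")
  writeBin(flags, con)
  # uint64 seed stored as two little-endian 32-bit words (seeds < 2^31)
  writeBin(as.integer(c(seed, 0L)), con, size = 4, endian = "little")
  vals <- as.vector(t(payload_matrix))          # row-major payload
  if (dtype == 0L) {
    writeBin(as.double(vals), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
  }
  invisible(path)
}

.read_container <- function(path, magic) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  got <- rawToChar(readBin(con, "raw", 8))
  if (!identical(got, magic))
    stop("bad magic in '", path, "': expected ", magic, ", got '", got, "'")
  dims <- readBin(con, "integer", 2, size = 4, endian = "little")
  dtype <- as.integer(readBin(con, "raw", 1))
  dbls <- readBin(con, "double", 5, size = 8, endian = "little")
  flags <- as.integer(readBin(con, "raw", 1))
  seed_words <- readBin(con, "integer", 2, size = 4, endian = "little")
  n <- dims[1] * dims[2]
  header_bytes <- 8 + 8 + 1 + 40 + 1 + 8
  elt <- if (dtype == 0L) 4 else 2
  expected <- header_bytes + n * elt
  if (sz != expected)
    stop("truncated or oversized payload in '", path, "': expected ",
         expected, " bytes, found ", sz)
  vals <- if (dtype == 0L) {
    readBin(con, "double", n, size = 4, endian = "little")
  } else {
    as.double(readBin(con, "integer", n, size = 2, signed = FALSE,
                      endian = "little"))
  }
  readings <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  if (dtype == 1L) readings <- readings * dbls[1] + dbls[2]
  list(readings = readings, dtype = dtype, scale = dbls[1], offset = dbls[2],
       kvp = dbls[3], ma = dbls[4], exposure = dbls[5], flags = flags,
       seed = seed_words[1])
}

#' Write a raw detector frame
#'
#' Bit-exact little-endian container: 8-byte magic `"CTRAW001"`, uint32
#' rows, uint32 channels, uint8 dtype (0 = float32, 1 = uint16 with
#' affine scale/offset), five float64 fields (scale, offset, kVp, mA,
#' exposure s), a uint8 flag byte (bit0 phantom, bit1 blocker, bit2
#' calibrated), a uint64 seed, then the row-major payload.  The uint16
#' dtype emulates the acquisition software's compression of high-valued
#' readings into a 16-bit range.
#'
#' @param frame a [detector_frame()]
#' @param path output file
#' @param compression `"none"` (float32 payload) or `"uint16"`
#' @export
write_frame <- function(frame, path, compression = c("none", "uint16")) {
  stopifnot(inherits(frame, "detector_frame"))
  compression <- match.arg(compression)
  m <- frame$meta
  r <- frame$readings
  if (compression == "none") {
    .write_container(path, .frame_magic, r, 0L, 1, 0, m$kvp, m$tube_current,
                     m$exposure_s, .pack_flags(m), m$seed)
  } else {
    lo <- min(r); hi <- max(r)
    scale <- max((hi - lo) / 65535, .Machine$double.eps)
    q <- (r - lo) / scale
    .write_container(path, .frame_magic, q, 1L, scale, lo, m$kvp,
                     m$tube_current, m$exposure_s, .pack_flags(m), m$seed)
  }
  invisible(path)
}

#' Read a raw detector frame
#'
#' Inverse of [write_frame()]; uint16-compressed payloads are expanded
#' through their stored scale and offset.
#'
#' @param path file written by [write_frame()]
#' @return a [detector_frame()]
#' @export
read_frame <- function(path) {
  x <- .read_container(path, .frame_magic)
  detector_frame(pmax(x$readings, 0),
                 kvp = x$kvp, tube_current = x$ma, exposure_s = x$exposure,
                 phantom_present = bitwAnd(x$flags, 1L) > 0,
                 blocker_present = bitwAnd(x$flags, 2L) > 0,
                 calibrated = bitwAnd(x$flags, 4L) > 0,
                 seed = x$seed)
}

#' Calibration table
#'
#' Per-element multiplicative gains applied by the scanner software;
#' [decalibrate()] inverts them to recover the unprocessed readings.
#'
#' @param gains positive matrix, rows x channels
#' @param compression `"none"` or `"uint16"` - how frames calibrated with
#'   this table are stored on disk
#' @export
calibration_table <- function(gains, compression = c("none", "uint16")) {
  gains <- as.matrix(gains)
  if (any(!is.finite(gains)) || any(gains <= 0))
    stop("all gains must be finite and positive")
  structure(list(gains = gains, compression = match.arg(compression)),
            class = "calibration_table")
}

#' Random per-element calibration table for a geometry
#'
#' Log-normal gains with the given log-sd, emulating unknown per-element
#' scanner calibration factors.
#'
#' @param geom a [scanner_geometry()]
#' @param seed RNG seed
#' @param sdlog log-sd of the gains
#' @inheritParams calibration_table
#' @export
make_calibration_table <- function(geom, seed = 1, sdlog = 0.05,
                                   compression = "none") {
  r <- with_local_seed(seed, matrix(
    exp(stats::rnorm(geom$n_rows * geom$n_channels_total, 0, sdlog)),
    geom$n_rows, geom$n_channels_total))
  calibration_table(r, compression)
}

#' Identity calibration table
#' @inheritParams make_calibration_table
#' @export
identity_calibration <- function(geom) {
  calibration_table(matrix(1, geom$n_rows, geom$n_channels_total))
}

#' Write / read a calibration table
#'
#' Same binary container as frames with magic `"CTCAL001"` and float32
#' gains payload.
#' @param table a [calibration_table()]
#' @param path file path
#' @export
write_calibration <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  .write_container(path, .cal_magic, table$gains,
                   0L, 1, 0, NA_real_, NA_real_, NA_real_,
                   as.raw(if (table$compression == "uint16") 1L else 0L), 0L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- .read_container(path, .cal_magic)
  calibration_table(x$readings,
                    if (x$flags == 1L) "uint16" else "none")
}

#' Apply scanner calibration to a frame
#'
#' Multiplies readings elementwise by the gains and marks the frame
#' calibrated; the emulated scanner software hands over frames in this
#' state.
#' @param frame a [detector_frame()]
#' @param table a [calibration_table()]
#' @export
calibrate <- function(frame, table) {
  .check_cal(frame, table, want_calibrated = FALSE)
  frame$readings <- frame$readings * table$gains
  frame$meta$calibrated <- TRUE
  frame
}

#' Invert scanner calibration
#'
#' Divides readings elementwise by the gains and clears the calibrated
#' flag, recovering the untainted detector data.  Exact inverse of
#' [calibrate()] up to float tolerance when compression is `"none"`, and
#' up to half a quantisation step when frames passed through uint16
#' storage.
#' @inheritParams calibrate
#' @export
decalibrate <- function(frame, table) {
  .check_cal(frame, table, want_calibrated = TRUE)
  frame$readings <- frame$readings / table$gains
  frame$meta$calibrated <- FALSE
  frame
}

.check_cal <- function(frame, table, want_calibrated) {
  stopifnot(inherits(frame, "detector_frame"),
            inherits(table, "calibration_table"))
  if (!identical(dim(frame$readings), dim(table$gains)))
    stop("frame (", paste(dim(frame$readings), collapse = "x"),
         ") and calibration table (",
         paste(dim(table$gains), collapse = "x"), ") shapes differ")
  if (frame$meta$calibrated != want_calibrated)
    stop("frame calibrated flag is ", frame$meta$calibrated,
         "; expected ", want_calibrated)
  invisible(TRUE)
}

# run code under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
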