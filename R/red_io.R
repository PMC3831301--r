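## Experiment-information file and frame-stack I/O.
##
## A rotation-ED dataset is a directory of MRC frames plus one plain-text
## information file carrying the electron wavelength, the reciprocal-space
## sampling (pixels per reciprocal Angstrom), the tilt-axis azimuth and one
## row per frame with goniometer, beam and combined tilt. The dialect is:
##
##   WAVELENGTH 0.0251
##   PIXELS_PER_RECIPROCAL_ANGSTROM 280.0
##   TILT_AXIS_DEG 48.5
##   DETECTOR 512 512
##   BIT_DEPTH 12
##   <blank line>
##   frame_0001.mrc  -60.0000  -1.0000  -61.0000
##   ...

#' Experiment information
#'
#' Container for the metadata of a rotation-ED dataset.
#'
#' @param wavelength electron wavelength in Angstrom (e.g. 0.0251 at 200 kV).
#' @param pixels_per_inv_angstrom detector sampling in pixels per reciprocal
#'   Angstrom.
#' @param tilt_axis_azimuth azimuth of the tilt axis in degrees,
#'   counterclockwise from the detector +x axis; the axis lies in the
#'   detector plane.
#' @param frames data.frame with columns `filename`, `goniometer_tilt`,
#'   `beam_tilt`, `combined_tilt` (degrees).
#' @param detector_shape integer(2), (rows, cols) in pixels.
#' @param bit_depth camera dynamic range; saturation level is
#'   `2^bit_depth - 1`.
#' @return object of class `experiment_info`.
#' @export
experiment_info <- function(wavelength, pixels_per_inv_angstrom,
                            tilt_axis_azimuth, frames,
                            detector_shape = c(512L, 512L), bit_depth = 12L) {
  stopifnot(is.numeric(wavelength), wavelength > 0,
            is.numeric(pixels_per_inv_angstrom), pixels_per_inv_angstrom > 0,
            is.data.frame(frames), nrow(frames) >= 1,
            all(c("filename", "goniometer_tilt", "beam_tilt",
                  "combined_tilt") %in% names(frames)),
            length(detector_shape) == 2, all(detector_shape > 0),
            bit_depth >= 1)
  if (max(abs(frames$combined_tilt - frames$goniometer_tilt -
                frames$beam_tilt)) > 1e-6)
    stop("combined tilt is not the sum of goniometer and beam tilt")
  ## combined tilts must be strictly ordered once overlap frames are removed
  ct <- round(frames$combined_tilt, 5)
  uct <- ct[!duplicated(ct)]
  if (any(diff(uct) <= 0) && any(diff(uct) >= 0) && length(uct) > 1) {
    if (!(all(diff(uct) > 0) || all(diff(uct) < 0)))
      stop("combined tilts are not strictly ordered after deduplication")
  }
  structure(list(wavelength = wavelength,
                 pixels_per_inv_angstrom = pixels_per_inv_angstrom,
                 tilt_axis_azimuth = tilt_axis_azimuth,
                 frames = frames,
                 detector_shape = as.integer(detector_shape),
                 bit_depth = as.integer(bit_depth)),
            class = "experiment_info")
}

#' @export
print.experiment_info <- function(x, ...) {
  cat(sprintf(paste0("rotation-ED experiment: %d frames, lambda=%.4f A, ",
                     "%.1f px/A^-1, tilt axis %.2f deg, %dx%d px, %d bit\n"),
              nrow(x$frames), x$wavelength, x$pixels_per_inv_angstrom,
              x$tilt_axis_azimuth, x$detector_shape[1], x$detector_shape[2],
              x$bit_depth))
  cat(sprintf("combined tilt %.2f to %.2f deg\n",
              min(x$frames$combined_tilt), max(x$frames$combined_tilt)))
  invisible(x)
}

#' Parse an experiment-information file
#'
#' @param path path of the plain-text information file.
#' @return [experiment_info()] object. Combined tilts are recomputed from the
#'   goniometer and beam columns and checked against the stored values.
#' @export
parse_info_file <- function(path) {
  if (!file.exists(path)) stop("info file not found: ", path)
  lines <- readLines(path)
  grab <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(hit) != 1)
      stop("info file format error: missing or duplicated key ", key)
    strsplit(trimws(hit), "\\s+")[[1]][-1]
  }
  wavelength <- as.numeric(grab("WAVELENGTH"))
  ppa <- as.numeric(grab("PIXELS_PER_RECIPROCAL_ANGSTROM"))
  axis <- as.numeric(grab("TILT_AXIS_DEG"))
  det <- as.integer(grab("DETECTOR"))
  bits <- as.integer(grab("BIT_DEPTH"))
  blank <- which(!nzchar(trimws(lines)))[1]
  if (is.na(blank)) stop("info file format error: missing blank separator line")
  if (blank >= length(lines)) stop("info file format error: zero frame rows")
  rows <- trimws(lines[seq(blank + 1, length(lines))])
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0) stop("info file format error: zero frame rows")
  parts <- strsplit(rows, "\\s+")
  if (any(lengths(parts) != 4))
    stop("info file format error: frame rows must have 4 columns")
  frames <- data.frame(
    filename = vapply(parts, `[`, "", 1),
    goniometer_tilt = as.numeric(vapply(parts, `[`, "", 2)),
    beam_tilt = as.numeric(vapply(parts, `[`, "", 3)),
    combined_tilt = as.numeric(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  if (max(abs(frames$combined_tilt -
                (frames$goniometer_tilt + frames$beam_tilt))) > 1e-4)
    stop("info file format error: combined tilt != goniometer + beam tilt")
  frames$combined_tilt <- frames$goniometer_tilt + frames$beam_tilt
  experiment_info(wavelength, ppa, axis, frames, det, bits)
}

#' Write an experiment-information file
#'
#' Inverse of [parse_info_file()]; angles are serialized with 6 decimals so
#' fine beam-tilt steps survive the round trip, and two writes of the same
#' object are byte-identical.
#'
#' @param info [experiment_info()] object.
#' @param path output path.
#' @export
write_info_file <- function(info, path) {
  stopifnot(inherits(info, "experiment_info"))
  f <- info$frames
  lines <- c(
    sprintf("WAVELENGTH %.6f", info$wavelength),
    sprintf("PIXELS_PER_RECIPROCAL_ANGSTROM %.6f",
            info$pixels_per_inv_angstrom),
    sprintf("TILT_AXIS_DEG %.6f", info$tilt_axis_azimuth),
    sprintf("DETECTOR %d %d", info$detector_shape[1], info$detector_shape[2]),
    sprintf("BIT_DEPTH %d", info$bit_depth),
    "",
    sprintf("%s %.6f %.6f %.6f", f$filename, f$goniometer_tilt, f$beam_tilt,
            f$combined_tilt))
  writeLines(lines, path)
  invisible(path)
}

#' Read the MRC frames of a dataset
#'
#' @param info [experiment_info()] object.
#' @param dir directory holding the MRC files named in `info$frames`.
#' @return list with `images` (list of matrices in frame order) and
#'   `saturated` (list of logical matrices flagging pixels at
#'   `2^bit_depth - 1`).
#' @export
read_frame_stack <- function(info, dir) {
  stopifnot(inherits(info, "experiment_info"))
  sat_level <- 2^info$bit_depth - 1
  images <- vector("list", nrow(info$frames))
  saturated <- vector("list", nrow(info$frames))
  for (i in seq_len(nrow(info$frames))) {
    p <- file.path(dir, info$frames$filename[i])
    if (!file.exists(p)) stop("missing frame file: ", p)
    m <- read_mrc(p)
    if (!all(dim(m) == info$detector_shape))
      stop("frame ", info$frames$filename[i], " has shape ",
           paste(dim(m), collapse = "x"), ", expected ",
           paste(info$detector_shape, collapse = "x"))
    images[[i]] <- m
    saturated[[i]] <- m >= sat_level
  }
  list(images = images, saturated = saturated)
}

#' Tilt schedule of a rotation-ED collection
#'
#' The collection alternates fine beam-tilt sweeps of `+/- beam_half_range`
#' in `beam_step` increments with coarse goniometer steps of
#' `goniometer_step`; when the beam half-range exceeds half the goniometer
#' step, consecutive sweeps share frames with equal combined tilt.
#'
#' @param goniometer_start,goniometer_stop goniometer range in degrees.
#' @param goniometer_step goniometer increment in degrees (> 0).
#' @param beam_half_range beam-tilt half range alpha in degrees (>= 0).
#' @param beam_step beam-tilt increment in degrees (> 0).
#' @return object of class `tilt_schedule`.
#' @export
tilt_schedule <- function(goniometer_start, goniometer_stop, goniometer_step,
                          beam_half_range, beam_step) {
  stopifnot(beam_step > 0, beam_half_range >= 0, goniometer_step > 0,
            goniometer_stop >= goniometer_start)
  structure(list(goniometer_start = goniometer_start,
                 goniometer_stop = goniometer_stop,
                 goniometer_step = goniometer_step,
                 beam_half_range = beam_half_range,
                 beam_step = beam_step),
            class = "tilt_schedule")
}

#' Enumerate the frames of a tilt schedule
#'
#' @param sched [tilt_schedule()] object.
#' @return data.frame with columns `goniometer_tilt`, `beam_tilt`,
#'   `combined_tilt` (degrees), one row per frame in collection order. Per
#'   goniometer position the beam runs `-alpha ... +alpha` inclusive, so each
#'   sweep has `round(2 * alpha / beam_step) + 1` frames.
#' @export
build_tilt_schedule <- function(sched) {
  stopifnot(inherits(sched, "tilt_schedule"))
  n_beam <- round(2 * sched$beam_half_range / sched$beam_step) + 1
  beam <- if (n_beam == 1) 0 else
    seq(-sched$beam_half_range, sched$beam_half_range, length.out = n_beam)
  gonio <- seq(sched$goniometer_start, sched$goniometer_stop,
               by = sched$goniometer_step)
  out <- data.frame(
    goniometer_tilt = rep(gonio, each = n_beam),
    beam_tilt = rep(beam, times = length(gonio)))
  out$combined_tilt <- out$goniometer_tilt + out$beam_tilt
  out
}
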