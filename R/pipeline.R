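## Configuration-driven orchestration of the full reduction:
## read -> shift correction -> peak hunting -> reconstruction -> merging ->
## basis/cell -> indexing -> export. Frames are processed one at a time so
## memory stays flat regardless of stack size, and the whole run is
## deterministic: identical config gives identical outputs.

#' Pipeline configuration
#'
#' @param input_dir directory with the MRC frames and information file.
#' @param info_file information file name inside `input_dir`.
#' @param out_dir run directory for all artifacts (created; default
#'   `file.path(input_dir, "red_out")`).
#' @param tilt_axis `"info"` (use the azimuth stored in the information
#'   file), `"refine"` (run the straightness scan), or a numeric azimuth in
#'   degrees.
#' @param do_shift_correction toggle for the drift stage; when off, all
#'   shifts are zero and the nominal beam position of frame 1 is used
#'   throughout.
#' @param roi_halfsize cross-correlation ROI half-size in pixels.
#' @param peak_params [peak_hunt_params()] object.
#' @param intensity_mode per-spot intensity used downstream: `"max"`
#'   (maximum pixel, default), `"smoothed"` or `"integrated"`.
#' @param window_radius,annulus_width 2D integration geometry in pixels.
#' @param merge_2d_radius,merge_3d_radius,max_frame_gap see [merge_spots()].
#' @param index_threshold per-axis indexing threshold (default 0.1).
#' @param refine_scan scan grid for `tilt_axis = "refine"`,
#'   `c(start, stop, coarse, fine)` degrees.
#' @param export_mode intensity written to the HKLF4 file: `"max"` or
#'   `"3d"`.
#' @param cell_transform optional 3x3 integer matrix applied to the found
#'   basis before cell derivation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, info_file = "experiment.info",
                            out_dir = file.path(input_dir, "red_out"),
                            tilt_axis = "info",
                            do_shift_correction = TRUE,
                            roi_halfsize = 128,
                            peak_params = peak_hunt_params(),
                            intensity_mode = c("max", "smoothed",
                                               "integrated"),
                            window_radius = 5, annulus_width = 3,
                            merge_2d_radius = 6, merge_3d_radius = 0.0075,
                            max_frame_gap = 2, index_threshold = 0.1,
                            refine_scan = c(0, 180, 0.5, 0.1),
                            export_mode = c("max", "3d"),
                            cell_transform = NULL) {
  intensity_mode <- match.arg(intensity_mode)
  export_mode <- match.arg(export_mode)
  structure(list(input_dir = input_dir, info_file = info_file,
                 out_dir = out_dir, tilt_axis = tilt_axis,
                 do_shift_correction = do_shift_correction,
                 roi_halfsize = roi_halfsize, peak_params = peak_params,
                 intensity_mode = intensity_mode,
                 window_radius = window_radius,
                 annulus_width = annulus_width,
                 merge_2d_radius = merge_2d_radius,
                 merge_3d_radius = merge_3d_radius,
                 max_frame_gap = max_frame_gap,
                 index_threshold = index_threshold,
                 refine_scan = refine_scan, export_mode = export_mode,
                 cell_transform = cell_transform),
            class = "pipeline_config")
}

## Sub-pixel direct-beam position: intensity-weighted centroid of the
## half-maximum region around the brightest ROI pixel (robust to the
## saturated plateau of the beam, which stays symmetric).
locate_beam <- function(frame, roi_centre, roi_halfsize, win = 10) {
  roi <- crop_roi(frame, roi_centre, roi_halfsize)
  imax <- which.max(roi)
  ry <- (imax - 1) %% nrow(roi)
  rx <- (imax - 1) %/% nrow(roi)
  x0 <- round(roi_centre[1]) - roi_halfsize + rx
  y0 <- round(roi_centre[2]) - roi_halfsize + ry
  xs <- max(0, x0 - win):min(ncol(frame) - 1, x0 + win)
  ys <- max(0, y0 - win):min(nrow(frame) - 1, y0 + win)
  w <- frame[ys + 1, xs + 1]
  w <- pmax(w - max(w) / 2, 0)
  c(x = sum(outer(rep(1, length(ys)), xs) * w) / sum(w),
    y = sum(outer(ys, rep(1, length(xs))) * w) / sum(w))
}

#' Run the full data-reduction pipeline
#'
#' @param config [pipeline_config()] object.
#' @return list with `info`, `shifts`, `beam_track` (per-frame beam
#'   positions), `spots` (beam-centred 2D spots), `spots3d`, `axis`
#'   (`tilt_axis`, with the score curve when refined), `reflections`,
#'   `basis`, `cell`, `indexed`, `absences`, `rint`, `hkl_path` and
#'   `out_dir`. All artifacts are also written as plain-text files into
#'   `out_dir`, together with `run.log` recording every parameter used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "",
                              file = logfile, append = TRUE)
  cat(sprintf("red3d pipeline run\n"), file = logfile)
  logmsg("parameters:")
  for (nm in setdiff(names(config), "peak_params"))
    logmsg("  %s = %s", nm, paste(format(config[[nm]]), collapse = " "))
  for (nm in names(config$peak_params))
    logmsg("  peak_params$%s = %s", nm, format(config$peak_params[[nm]]))

  info <- parse_info_file(file.path(config$input_dir, config$info_file))
  n_frames <- nrow(info$frames)
  nr <- info$detector_shape[1]; nc <- info$detector_shape[2]
  roi_centre <- c(nc / 2, nr / 2)
  sat_level <- 2^info$bit_depth - 1
  logmsg("stage read: %d frames of %dx%d px", n_frames, nr, nc)

  ## streaming pass: shift estimation + peak hunting per frame
  dx <- dy <- numeric(n_frames)
  spot_list <- vector("list", n_frames)
  acc <- NULL
  beam1 <- NULL
  for (i in seq_len(n_frames)) {
    frame <- read_mrc(file.path(config$input_dir, info$frames$filename[i]))
    if (!all(dim(frame) == c(nr, nc)))
      stop("stage read: frame ", info$frames$filename[i], " shape mismatch")
    if (config$do_shift_correction) {
      roi <- condition_roi(crop_roi(frame, roi_centre, config$roi_halfsize))
      if (i == 1) {
        acc <- roi
        beam1 <- locate_beam(frame, roi_centre, config$roi_halfsize)
      } else {
        sh <- xcorr_shift(acc, roi)
        dx[i] <- sh["dx"]; dy[i] <- sh["dy"]
        acc <- acc + .shift_bilinear_cpp(roi, -dx[i], -dy[i])
      }
    } else if (i == 1) {
      beam1 <- locate_beam(frame, roi_centre, config$roi_halfsize)
    }
    beam <- c(beam1[1] + dx[i], beam1[2] + dy[i])
    sp <- hunt_peaks(frame, config$peak_params, beam_centre = beam,
                     saturation_level = sat_level)
    if (nrow(sp) > 0) {
      sp <- extract_intensities(frame, sp, mode = "integrated",
                                window_radius = config$window_radius,
                                annulus_width = config$annulus_width)
      sp$frame <- i
      sp$x <- sp$x - beam[1]
      sp$y <- sp$y - beam[2]
      spot_list[[i]] <- sp
    }
  }
  shifts <- data.frame(frame = seq_len(n_frames), dx = dx, dy = dy)
  beam_track <- data.frame(frame = seq_len(n_frames),
                           x = beam1[1] + dx, y = beam1[2] + dy)
  spots <- do.call(rbind, spot_list[!vapply(spot_list, is.null, TRUE)])
  rownames(spots) <- NULL
  if (is.null(spots) || nrow(spots) < 10)
    stop("stage peaks: fewer than 10 spots found in the whole stack")
  logmsg("stage align: beam at (%.2f, %.2f), max |shift| %.2f px",
         beam1[1], beam1[2], max(abs(c(dx, dy))))
  logmsg("stage peaks: %d spots (%d saturated)", nrow(spots),
         sum(spots$saturated))
  write_shift_table(shifts, file.path(config$out_dir, "shifts.tsv"))
  write_spot_table(spots, file.path(config$out_dir, "spots2d.tsv"))

  ## intensity used downstream
  spots$I <- switch(config$intensity_mode,
                    max = spots$raw_peak,
                    smoothed = spots$smoothed_peak,
                    integrated = spots$integrated)

  ## tilt axis
  if (identical(config$tilt_axis, "refine")) {
    axis <- refine_tilt_axis(spots, info, scan = config$refine_scan)
    utils::write.table(attr(axis, "score_curve"),
                       file.path(config$out_dir, "axis_score.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    logmsg("stage axis: refined azimuth %.2f deg", axis$azimuth)
  } else if (identical(config$tilt_axis, "info")) {
    axis <- tilt_axis(info$tilt_axis_azimuth)
    logmsg("stage axis: using stored azimuth %.2f deg", axis$azimuth)
  } else {
    axis <- tilt_axis(as.numeric(config$tilt_axis))
    logmsg("stage axis: using user azimuth %.2f deg", axis$azimuth)
  }

  spots3d <- map_to_3d(spots, info, axis)
  utils::write.table(
    spots3d[, c("gx", "gy", "gz", "I", "frame")],
    file.path(config$out_dir, "spots3d.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  logmsg("stage reconstruct: %d spots after overlap deduplication",
         nrow(spots3d))

  refl <- merge_spots(spots3d, merge_2d_radius = config$merge_2d_radius,
                      merge_3d_radius = config$merge_3d_radius,
                      max_frame_gap = config$max_frame_gap,
                      intensity_col = "I")
  logmsg("stage merge: %d reflections", nrow(refl))

  basis0 <- find_reciprocal_basis(refl)
  ## first indexing pass, then least-squares basis refinement and re-index
  indexed0 <- index_reflections(refl, basis0,
                                index_params(config$index_threshold))
  basis <- tryCatch(refine_basis(indexed0), error = function(e) {
    logmsg("stage cell: basis refinement skipped (%s)", conditionMessage(e))
    basis0
  })
  cell <- cell_parameters_from_basis(basis, config$cell_transform)
  cell_path <- file.path(config$out_dir, "cell.txt")
  writeLines(c(utils::capture.output(print(cell)),
               "reciprocal basis (columns a*, b*, c*, 1/A):",
               utils::capture.output(print(unclass(basis)))), cell_path)
  logmsg("stage cell: a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f",
         cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)

  indexed <- index_reflections(refl, basis,
                               index_params(config$index_threshold))
  logmsg("stage index: %d of %d accepted", sum(indexed$accepted),
         nrow(indexed))
  write_reflection_table(indexed,
                         file.path(config$out_dir, "reflections.tsv"),
                         intensity_mode = config$export_mode)
  absences <- absence_statistics(indexed)
  utils::write.table(absences,
                     file.path(config$out_dir, "absences.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  hkl_path <- file.path(config$out_dir, "reflections.hkl")
  scale <- write_hklf4(indexed, hkl_path,
                       intensity_mode = config$export_mode)
  rint <- friedel_rint(indexed, intensity_mode = config$export_mode)
  logmsg("stage export: scale %.3g, Friedel R_int %.4f", scale, rint)
  logmsg("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  list(info = info, shifts = shifts, beam_track = beam_track,
       spots = spots, spots3d = spots3d, axis = axis,
       reflections = refl, basis = basis, cell = cell, indexed = indexed,
       absences = absences, rint = rint, hkl_path = hkl_path,
       out_dir = config$out_dir)
}
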