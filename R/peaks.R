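## Difference-of-Gaussians peak hunting and intensity extraction.
##
## A frame is smoothed twice: once with a wide Gaussian (background estimate,
## sigma typically > 10 px) and once with a narrow one (noise-suppressed
## diffraction frame, sigma 0.5-2 px). Pixels where the diffraction frame
## exceeds the background by a user threshold are grouped by 8-connectivity;
## each group becomes one spot at its maximum-intensity pixel.

#' Peak-hunting parameters
#'
#' @param background_sigma sigma of the wide background Gaussian in pixels
#'   (default 12).
#' @param signal_sigma sigma of the narrow smoothing Gaussian in pixels
#'   (default 1.0).
#' @param threshold counts above background required for a pixel to belong
#'   to a spot (default 20).
#' @param min_separation minimum spot separation in pixels; groups closer
#'   than this merge implicitly through connectivity (kept for reporting).
#' @param exclusion_radius radius around the direct beam inside which
#'   detections are dropped, in pixels (default 12).
#' @return object of class `peak_hunt_params`.
#' @export
peak_hunt_params <- function(background_sigma = 12, signal_sigma = 1.0,
                             threshold = 20, min_separation = 3,
                             exclusion_radius = 12) {
  stopifnot(background_sigma > signal_sigma, signal_sigma > 0, threshold > 0,
            exclusion_radius >= 0)
  structure(list(background_sigma = background_sigma,
                 signal_sigma = signal_sigma, threshold = threshold,
                 min_separation = min_separation,
                 exclusion_radius = exclusion_radius),
            class = "peak_hunt_params")
}

#' Hunt diffraction spots on one frame
#'
#' @param frame numeric matrix (`m[y + 1, x + 1]`, counts).
#' @param params [peak_hunt_params()] object.
#' @param beam_centre (x, y) of the direct beam in 0-based pixels, used for
#'   the exclusion disc; `NULL` disables the exclusion.
#' @param saturation_level counts at which a pixel is saturated (flags spots
#'   whose group touches such a pixel); `NULL` disables the flag.
#' @return data.frame with columns `x, y` (0-based detector pixels of the
#'   maximum of the smoothed frame within each group; ties broken towards
#'   the lowest (y, x)), `raw_peak`, `smoothed_peak`, `npix` (group size) and
#'   `saturated`.
#' @export
hunt_peaks <- function(frame, params = peak_hunt_params(),
                       beam_centre = NULL, saturation_level = NULL) {
  stopifnot(is.matrix(frame), inherits(params, "peak_hunt_params"))
  bg <- .gaussian_blur_cpp(frame, params$background_sigma)
  sig <- .gaussian_blur_cpp(frame, params$signal_sigma)
  mask <- sig > bg + params$threshold
  if (!any(mask)) return(empty_spots())
  lab <- .label_components_cpp(mask)
  idx <- which(lab > 0)
  comp <- lab[idx]
  vals <- sig[idx]
  nr <- nrow(frame)
  ys <- (idx - 1) %% nr          # 0-based row = y
  xs <- (idx - 1) %/% nr         # 0-based col = x
  ## per-component argmax of the smoothed frame; order by (value desc,
  ## y asc, x asc) so the first hit per component is the deterministic winner
  o <- order(comp, -vals, ys, xs)
  first <- o[!duplicated(comp[o])]
  px <- xs[first]; py <- ys[first]
  sat <- if (is.null(saturation_level)) rep(FALSE, length(first)) else
    as.vector(tapply(frame[idx] >= saturation_level, comp, any))
  npix <- as.vector(table(comp))
  out <- data.frame(x = px, y = py,
                    raw_peak = frame[cbind(py + 1, px + 1)],
                    smoothed_peak = sig[cbind(py + 1, px + 1)],
                    npix = npix, saturated = sat)
  if (!is.null(beam_centre) && params$exclusion_radius > 0) {
    r2 <- (out$x - beam_centre[1])^2 + (out$y - beam_centre[2])^2
    out <- out[r2 > params$exclusion_radius^2, , drop = FALSE]
  }
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_spots <- function() {
  data.frame(x = numeric(), y = numeric(), raw_peak = numeric(),
             smoothed_peak = numeric(), npix = integer(),
             saturated = logical())
}

#' Extract spot intensities
#'
#' Two modes. `"smoothed"` takes the value of the narrow-Gaussian smoothed
#' frame at the spot position (a weighted average of the pixels on and
#' around the maximum). `"integrated"` sums `pixel - local background` over
#' a disc of radius `window_radius`, where the background is the mean of the
#' annulus between `window_radius` and `window_radius + annulus_width`.
#'
#' @param frame numeric matrix.
#' @param spots data.frame from [hunt_peaks()].
#' @param mode `"smoothed"` or `"integrated"`.
#' @param window_radius inner disc radius in pixels (default 5).
#' @param annulus_width background annulus width in pixels (default 3).
#' @param signal_sigma sigma used for `"smoothed"` mode (default 1.0).
#' @return `spots` with an `integrated` (or refreshed `smoothed_peak`)
#'   column; windows clipped by the frame edge are flagged in `partial`.
#'   Small negative integrals (background fluctuation) are kept, not
#'   clamped.
#' @export
extract_intensities <- function(frame, spots, mode = c("integrated",
                                                       "smoothed"),
                                window_radius = 5, annulus_width = 3,
                                signal_sigma = 1.0) {
  mode <- match.arg(mode)
  if (nrow(spots) == 0) {
    spots$integrated <- numeric(0)
    spots$partial <- logical(0)
    return(spots)
  }
  nr <- nrow(frame); nc <- ncol(frame)
  if (mode == "smoothed") {
    sig <- .gaussian_blur_cpp(frame, signal_sigma)
    spots$smoothed_peak <- sig[cbind(spots$y + 1, spots$x + 1)]
    spots$integrated <- spots$smoothed_peak
    spots$partial <- FALSE
    return(spots)
  }
  rout <- window_radius + annulus_width
  ## precompute the offset stencil once
  off <- expand.grid(dx = -rout:rout, dy = -rout:rout)
  r2 <- off$dx^2 + off$dy^2
  inner <- r2 <= window_radius^2
  ring <- r2 > window_radius^2 & r2 <= rout^2
  integrated <- numeric(nrow(spots))
  partial <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    xs <- spots$x[i] + off$dx
    ys <- spots$y[i] + off$dy
    ok <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
    partial[i] <- !all(ok)
    v <- rep(NA_real_, length(xs))
    v[ok] <- frame[cbind(ys[ok] + 1, xs[ok] + 1)]
    bg <- mean(v[ring & ok], na.rm = TRUE)
    if (!is.finite(bg)) bg <- 0
    integrated[i] <- sum(v[inner & ok] - bg, na.rm = TRUE)
  }
  spots$integrated <- integrated
  spots$partial <- partial
  spots
}

#' Write a 2D spot table as TSV
#' @param spots data.frame of spots (with a `frame` column added upstream).
#' @param path output path.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
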