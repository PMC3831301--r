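## Direct-beam drift correction.
##
## The beam (and the whole pattern with it) drifts slowly during collection.
## Each frame's shift is measured by cross-correlating a small region of
## interest around the beam against the running shift-corrected sum of all
## previous frames, which suppresses noise in the reference as the stack
## progresses. Correlation peaks are refined to sub-pixel precision with a
## separable quadratic fit to the 3x3 neighbourhood.

## FFT cross-correlation of equally sized matrices; returns the shift of b
## relative to a (b approx a translated by +shift), sub-pixel refined.
xcorr_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  FA <- stats::fft(a); FB <- stats::fft(b)
  cc <- Re(stats::fft(FA * Conj(FB), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  imax <- which.max(cc)
  r0 <- (imax - 1) %% nr
  c0 <- (imax - 1) %/% nr
  ## wraparound convention: peak index p means b = a shifted by -p (mod n)
  wrap <- function(p, n) ifelse(p > n / 2, p - n, p)
  sub <- function(p, n, vals) {
    ## vals = c(before, centre, after) correlation values along one axis
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (den >= 0) return(0)       # not a proper maximum
    max(-0.5, min(0.5, 0.5 * (vals[1] - vals[3]) / den))
  }
  rp <- c((r0 - 1) %% nr, r0, (r0 + 1) %% nr) + 1
  cp <- c((c0 - 1) %% nc, c0, (c0 + 1) %% nc) + 1
  dr <- sub(r0, nr, cc[rp, c0 + 1])
  dc <- sub(c0, nc, cc[r0 + 1, cp])
  sh_r <- -(wrap(r0, nr) + dr)
  sh_c <- -(wrap(c0, nc) + dc)
  c(dx = sh_c, dy = sh_r)
}

## Background-subtract and clip an ROI so a strong Bragg spot wandering into
## the window cannot dominate the correlation.
condition_roi <- function(m, clip_q = 0.999) {
  m <- m - stats::median(m)
  pmin(m, stats::quantile(m, clip_q))
}

crop_roi <- function(img, centre, halfsize) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- round(centre[1]); y0 <- round(centre[2])
  xs <- (x0 - halfsize):(x0 + halfsize - 1)
  ys <- (y0 - halfsize):(y0 + halfsize - 1)
  if (min(xs) < 0 || max(xs) > nc - 1 || min(ys) < 0 || max(ys) > nr - 1)
    stop("ROI extends outside the detector")
  img[ys + 1, xs + 1]
}

#' Estimate per-frame drift of the direct beam
#'
#' Frame 1 defines the reference (shift 0, 0). For every later frame the ROI
#' is cross-correlated against the running sum of all previous
#' shift-corrected ROIs; the running sum is updated after each frame. The
#' estimate is deterministic and order-dependent by design.
#'
#' @param stack list of frame matrices, or the `$images` element of
#'   [read_frame_stack()] output, or that output itself.
#' @param roi_centre (x, y) centre of the region of interest in 0-based
#'   detector pixels; defaults to the detector centre.
#' @param roi_halfsize half-size of the square ROI in pixels (default 128,
#'   i.e. a 256 x 256 window).
#' @return data.frame of class `shift_table` with columns `frame, dx, dy`
#'   (pixels, sub-pixel resolution) and a logical `clamped` flag set when a
#'   correlation peak had no curvature (degenerate fit).
#' @export
estimate_shifts <- function(stack, roi_centre = NULL, roi_halfsize = 128) {
  if (is.list(stack) && !is.null(stack$images)) stack <- stack$images
  stopifnot(length(stack) >= 1)
  nr <- nrow(stack[[1]]); nc <- ncol(stack[[1]])
  if (is.null(roi_centre)) roi_centre <- c(nc / 2, nr / 2)
  n <- length(stack)
  dx <- dy <- numeric(n)
  clamped <- logical(n)
  ref <- condition_roi(crop_roi(stack[[1]], roi_centre, roi_halfsize))
  acc <- ref
  for (i in seq_len(n)[-1]) {
    roi <- condition_roi(crop_roi(stack[[i]], roi_centre, roi_halfsize))
    sh <- xcorr_shift(acc, roi)
    if (max(abs(sh)) > roi_halfsize / 2) {
      clamped[i] <- TRUE
      sh <- pmax(pmin(sh, roi_halfsize / 2), -roi_halfsize / 2)
      warning("correlation peak near ROI border on frame ", i,
              "; shift clamped")
    }
    dx[i] <- sh["dx"]; dy[i] <- sh["dy"]
    ## align this ROI back onto the reference and accumulate
    acc <- acc + .shift_bilinear_cpp(roi, -dx[i], -dy[i])
  }
  structure(data.frame(frame = seq_len(n), dx = dx, dy = dy,
                       clamped = clamped),
            class = c("shift_table", "data.frame"),
            roi_centre = roi_centre, roi_halfsize = roi_halfsize)
}

#' Resample a stack so the direct beam sits at the reference position
#'
#' Bilinear interpolation; integer shifts reduce to pure pixel translation.
#' The alternative (and pipeline default) is to leave the images untouched
#' and correct spot coordinates only, which avoids resampling bias.
#'
#' @param stack list of frame matrices (or [read_frame_stack()] output, in
#'   which case the saturation masks are translated identically).
#' @param shifts [estimate_shifts()] result (columns `frame, dx, dy`).
#' @return object of the same shape as `stack` with each frame translated by
#'   `(-dx, -dy)`.
#' @export
apply_shifts <- function(stack, shifts) {
  masks <- NULL
  if (is.list(stack) && !is.null(stack$images)) {
    masks <- stack$saturated
    stack <- stack$images
  }
  stopifnot(all(is.finite(shifts$dx)), all(is.finite(shifts$dy)),
            length(stack) == nrow(shifts))
  out <- vector("list", length(stack))
  outm <- if (is.null(masks)) NULL else vector("list", length(stack))
  for (i in seq_along(stack)) {
    if (shifts$dx[i] == 0 && shifts$dy[i] == 0) {
      out[[i]] <- stack[[i]]
      if (!is.null(masks)) outm[[i]] <- masks[[i]]
    } else {
      out[[i]] <- .shift_bilinear_cpp(stack[[i]], -shifts$dx[i], -shifts$dy[i])
      if (!is.null(masks))
        outm[[i]] <- .shift_bilinear_cpp(masks[[i]] * 1, -shifts$dx[i],
                                         -shifts$dy[i]) > 0.5
    }
  }
  if (is.null(masks)) out else list(images = out, saturated = outm)
}

#' Write a shift table as TSV
#' @param shifts [estimate_shifts()] result.
#' @param path output path.
#' @export
write_shift_table <- function(shifts, path) {
  utils::write.table(shifts[, c("frame", "dx", "dy")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
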