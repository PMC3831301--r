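## Forward model of a rotation-ED experiment.
##
## The simulator holds a reciprocal lattice in a fixed crystal frame, rotates
## it into the lab frame with the exact inverse of the rotation the
## reconstruction applies, intersects it with the Ewald sphere (Gaussian
## rocking profile in excitation error), and renders each visible reflection
## as a 2D Gaussian on a 12-bit detector with flat background, Poisson noise
## and a drifting direct beam. Everything is driven by one integer seed, and
## equal seeds give byte-identical MRC output.

#' Enumerate reciprocal-lattice points to a resolution limit
#'
#' @param cell [unit_cell()] object.
#' @param d_min resolution limit in Angstrom; all reflections with
#'   `|g| <= 1/d_min` except 000 are returned.
#' @return data.frame with columns `h,k,l`, crystal-frame components
#'   `gx,gy,gz` (reciprocal Angstrom) and `d` (Angstrom).
#' @export
enumerate_reflections <- function(cell, d_min) {
  stopifnot(inherits(cell, "unit_cell"), d_min > 0)
  A <- real_space_matrix(cell)
  B <- t(solve(A))
  gmax <- 1 / d_min
  ## |h| <= |a| * gmax etc. because h = g . a
  lim <- ceiling(sqrt(colSums(A^2)) * gmax)
  hkl <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                               l = -lim[3]:lim[3]))
  g <- hkl %*% t(B)
  glen2 <- rowSums(g^2)
  keep <- glen2 <= gmax^2 & glen2 > 0
  out <- data.frame(hkl[keep, , drop = FALSE], g[keep, , drop = FALSE])
  names(out) <- c("h", "k", "l", "gx", "gy", "gz")
  out$d <- 1 / sqrt(glen2[keep])
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
}

#' Simulation configuration
#'
#' Defaults describe the reference experiment used throughout the test suite:
#' a monoclinic zeolite-like cell measured over a 120 degree tilt range in
#' 0.2 degree effective steps on a 12-bit 512x512 camera at 200 kV.
#'
#' @param cell [unit_cell()]; default a = 20.02, b = 20.25, c = 13.35 A,
#'   beta = 90.74 deg.
#' @param orientation 3x3 rotation matrix, crystal to lab frame at combined
#'   tilt 0; `NULL` draws a uniformly random orientation from the seed.
#' @param tilt_axis_azimuth_true true tilt-axis azimuth in degrees (48.5).
#' @param schedule [tilt_schedule()]; default goniometer -60..+60 deg in
#'   2 deg steps with beam tilt +/-1.0 deg in 0.2 deg steps (overlap frames
#'   at every sweep boundary).
#' @param wavelength electron wavelength in Angstrom (0.0251, 200 kV).
#' @param pixels_per_inv_angstrom detector sampling (280 px per 1/A).
#' @param detector_shape integer(2) (rows, cols).
#' @param d_min resolution limit in Angstrom (1.2).
#' @param rocking_halfwidth excitation-error scale zeta in 1/A (0.003); a
#'   reflection is visible while `|s| <= 3 * zeta` and attenuated by
#'   `exp(-s^2 / (2 zeta^2))`.
#' @param psf_sigma point-spread sigma of a spot in pixels (1.2).
#' @param background_level flat background in counts (50).
#' @param poisson_noise logical; apply Poisson counting noise.
#' @param drift_step_sigma per-frame sigma of the direct-beam random walk in
#'   pixels (0.2).
#' @param bit_depth camera depth (12); saturation at `2^bit_depth - 1`.
#' @param intensity_range reference peak intensities are drawn log-uniformly
#'   over this range in counts (c(40, 4000), two decades), one value per
#'   Friedel pair so that I(hkl) = I(-h,-k,-l) exactly.
#' @param beam_sigma,beam_amplitude direct-beam Gaussian footprint sigma (px)
#'   and peak counts (saturates the camera, as in experiments).
#' @param extinction optional `function(h, k, l)` returning TRUE for
#'   reflections to extinguish (reference intensity forced to zero), used to
#'   emulate systematic absences.
#' @param seed integer seed controlling orientation, intensities, drift and
#'   noise.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(cell = unit_cell(20.02, 20.25, 13.35, 90, 90.74, 90),
                       orientation = NULL,
                       tilt_axis_azimuth_true = 48.5,
                       schedule = tilt_schedule(-60, 60, 2, 1.0, 0.2),
                       wavelength = 0.0251,
                       pixels_per_inv_angstrom = 280,
                       detector_shape = c(512L, 512L),
                       d_min = 1.2,
                       rocking_halfwidth = 0.003,
                       psf_sigma = 1.2,
                       background_level = 50,
                       poisson_noise = TRUE,
                       drift_step_sigma = 0.2,
                       bit_depth = 12L,
                       intensity_range = c(40, 4000),
                       beam_sigma = 2.5,
                       beam_amplitude = 6e4,
                       extinction = NULL,
                       seed = 1L) {
  stopifnot(d_min > wavelength, rocking_halfwidth > 0, psf_sigma > 0,
            background_level >= 0, drift_step_sigma >= 0,
            length(intensity_range) == 2, all(intensity_range > 0))
  structure(list(cell = cell, orientation = orientation,
                 tilt_axis_azimuth_true = tilt_axis_azimuth_true,
                 schedule = schedule, wavelength = wavelength,
                 pixels_per_inv_angstrom = pixels_per_inv_angstrom,
                 detector_shape = as.integer(detector_shape), d_min = d_min,
                 rocking_halfwidth = rocking_halfwidth, psf_sigma = psf_sigma,
                 background_level = background_level,
                 poisson_noise = poisson_noise,
                 drift_step_sigma = drift_step_sigma,
                 bit_depth = as.integer(bit_depth),
                 intensity_range = intensity_range, beam_sigma = beam_sigma,
                 beam_amplitude = beam_amplitude, extinction = extinction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Uniformly random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## Resolve orientation + lab-frame lattice for a config (seed-deterministic:
## the orientation draw is the first use of the seed).
sim_lattice <- function(config) {
  set.seed(config$seed)
  O <- config$orientation
  if (is.null(O)) O <- random_rotation()
  refl <- enumerate_reflections(config$cell, config$d_min)
  if (!is.null(config$extinction)) {
    ext <- config$extinction(refl$h, refl$k, refl$l)
    refl <- refl[!ext, , drop = FALSE]
  }
  P <- as.matrix(refl[, c("gx", "gy", "gz")]) %*% t(O)  # lab frame at tilt 0
  ## one reference intensity per Friedel pair, log-uniform
  key_fwd <- paste(refl$h, refl$k, refl$l)
  key_rev <- paste(-refl$h, -refl$k, -refl$l)
  canon <- ifelse(key_fwd < key_rev, key_fwd, key_rev)
  ukeys <- unique(canon)
  lo <- log10(config$intensity_range[1]); hi <- log10(config$intensity_range[2])
  ui <- 10^stats::runif(length(ukeys), lo, hi)
  refl$intensity <- ui[match(canon, ukeys)]
  B_lab <- O %*% reciprocal_matrix(config$cell)
  list(refl = refl, P = P, orientation = O, basis_lab = B_lab)
}

## Distance from the flat detector plane origin to the Ewald sphere along z
## for transverse radius t (1/A): the sphere passes through the origin with
## centre (0, 0, 1/lambda).
ewald_z <- function(t2, wavelength) {
  r <- 1 / wavelength
  r - sqrt(r^2 - t2)
}

#' Project the lattice onto one frame
#'
#' Computes the ground-truth spot list for a single combined tilt: the
#' crystal-frame lattice is rotated by the exact inverse of the
#' reconstruction rotation about the true axis, and every reflection whose
#' excitation error `s` (signed distance from the Ewald sphere along the
#' beam axis) satisfies `|s| <= 3 * zeta` appears with relative intensity
#' `exp(-s^2 / (2 zeta^2))`.
#'
#' @param config [sim_config()] object.
#' @param combined_tilt frame rotation angle in degrees.
#' @param lattice optional precomputed result of the internal lattice setup
#'   (used by [render_dataset()] to avoid re-enumeration).
#' @return data.frame with `h,k,l`, beam-centred detector coordinates `x,y`
#'   (pixels), `relative_intensity`, excitation error `s` (1/A), and the
#'   rotated Ewald-sphere position `rx,ry,rz` (1/A) that an ideal
#'   reconstruction recovers.
#' @export
frame_projection <- function(config, combined_tilt, lattice = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(lattice)) lattice <- sim_lattice(config)
  zeta <- config$rocking_halfwidth
  phi <- config$tilt_axis_azimuth_true
  q <- rotate_rows_about_azimuth(lattice$P, phi, -combined_tilt)
  t2 <- q[, 1]^2 + q[, 2]^2
  r <- 1 / config$wavelength
  ok <- t2 < r^2
  s <- rep(NA_real_, nrow(q))
  s[ok] <- q[ok, 3] - ewald_z(t2[ok], config$wavelength)
  vis <- ok & !is.na(s) & abs(s) <= 3 * zeta
  if (!any(vis)) {
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      x = numeric(), y = numeric(),
                      relative_intensity = numeric(), s = numeric(),
                      rx = numeric(), ry = numeric(), rz = numeric()))
  }
  qv <- q[vis, , drop = FALSE]
  sphere <- cbind(qv[, 1], qv[, 2], ewald_z(qv[, 1]^2 + qv[, 2]^2,
                                            config$wavelength))
  rec <- rotate_rows_about_azimuth(sphere, phi, combined_tilt)
  ppa <- config$pixels_per_inv_angstrom
  out <- data.frame(h = lattice$refl$h[vis], k = lattice$refl$k[vis],
                    l = lattice$refl$l[vis],
                    x = qv[, 1] * ppa, y = qv[, 2] * ppa,
                    relative_intensity = exp(-s[vis]^2 / (2 * zeta^2)),
                    s = s[vis], rx = rec[, 1], ry = rec[, 2], rz = rec[, 3])
  rownames(out) <- NULL
  out
}

## Add a 2D Gaussian at (x0, y0) scaled so its maximum *pixel* equals `peak`.
add_gaussian <- function(img, x0, y0, sigma, peak, halfwidth) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- round(x0); cy <- round(y0)
  x_lo <- max(0, cx - halfwidth); x_hi <- min(nc - 1, cx + halfwidth)
  y_lo <- max(0, cy - halfwidth); y_hi <- min(nr - 1, cy + halfwidth)
  if (x_lo > x_hi || y_lo > y_hi) return(img)
  xs <- x_lo:x_hi; ys <- y_lo:y_hi
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  blob <- outer(gy, gx)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + peak / max(blob) * blob
  img
}

#' Render a complete simulated dataset
#'
#' Writes one uint16 MRC file per frame plus the experiment-information file
#' and plain-text ground truth (`truth_spots.tsv`, `truth_basis.tsv`,
#' `truth_drift.tsv`, `truth_intensities.tsv`) into `outdir`.
#'
#' @param config [sim_config()] object.
#' @param outdir output directory (created if needed).
#' @return list with `info` ([experiment_info()]) and `truth` (list with
#'   `spots` per-frame ground truth including drifted detector positions,
#'   `basis_lab` true lab-frame reciprocal basis (columns), `drift` beam
#'   track, `ref_intensities` per-hkl reference intensities, `orientation`).
#' @export
render_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lattice <- sim_lattice(config)   # seeds, draws orientation + intensities
  sched <- build_tilt_schedule(config$schedule)
  n_frames <- nrow(sched)
  nr <- config$detector_shape[1]; nc <- config$detector_shape[2]
  centre <- c((nc - 1) / 2, (nr - 1) / 2)
  ## beam random walk (drawn before any per-frame noise, frame 1 at centre)
  steps <- matrix(stats::rnorm(2 * n_frames, 0, config$drift_step_sigma),
                  ncol = 2)
  steps[1, ] <- 0
  drift <- apply(steps, 2, cumsum)
  if (n_frames == 1) drift <- matrix(drift, ncol = 2)
  sat <- 2^config$bit_depth - 1
  spot_hw <- as.integer(ceiling(5 * config$psf_sigma) + 1)
  beam_hw <- as.integer(ceiling(5 * config$beam_sigma) + 1)
  fnames <- sprintf("frame_%04d.mrc", seq_len(n_frames))
  truth_spots <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    proj <- frame_projection(config, sched$combined_tilt[f], lattice)
    key <- paste(proj$h, proj$k, proj$l)
    lkey <- paste(lattice$refl$h, lattice$refl$k, lattice$refl$l)
    ref_int <- lattice$refl$intensity[match(key, lkey)]
    bx <- centre[1] + drift[f, 1]; by <- centre[2] + drift[f, 2]
    x_abs <- proj$x + bx; y_abs <- proj$y + by
    inside <- x_abs > -spot_hw & x_abs < nc - 1 + spot_hw &
              y_abs > -spot_hw & y_abs < nr - 1 + spot_hw
    img <- matrix(config$background_level, nr, nc)
    img <- add_gaussian(img, bx, by, config$beam_sigma,
                        config$beam_amplitude, beam_hw)
    I_att <- ref_int * proj$relative_intensity
    for (i in which(inside)) {
      img <- add_gaussian(img, x_abs[i], y_abs[i], config$psf_sigma,
                          I_att[i], spot_hw)
    }
    if (config$poisson_noise) {
      img <- matrix(stats::rpois(nr * nc, pmax(img, 0)), nr, nc)
    } else {
      img <- round(img)
    }
    img <- pmin(img, sat)
    write_mrc(img, file.path(outdir, fnames[f]), mode = 6L)
    if (any(inside)) {
      truth_spots[[f]] <- data.frame(
        frame = f, h = proj$h[inside], k = proj$k[inside], l = proj$l[inside],
        x = x_abs[inside], y = y_abs[inside], intensity = I_att[inside],
        s = proj$s[inside], rx = proj$rx[inside], ry = proj$ry[inside],
        rz = proj$rz[inside])
    }
  }
  frames <- data.frame(filename = fnames,
                       goniometer_tilt = sched$goniometer_tilt,
                       beam_tilt = sched$beam_tilt,
                       combined_tilt = sched$combined_tilt,
                       stringsAsFactors = FALSE)
  info <- experiment_info(config$wavelength, config$pixels_per_inv_angstrom,
                          config$tilt_axis_azimuth_true, frames,
                          config$detector_shape, config$bit_depth)
  write_info_file(info, file.path(outdir, "experiment.info"))
  spots <- do.call(rbind, truth_spots[!vapply(truth_spots, is.null, TRUE)])
  rownames(spots) <- NULL
  drift_df <- data.frame(frame = seq_len(n_frames),
                         dx = drift[, 1], dy = drift[, 2])
  utils::write.table(spots, file.path(outdir, "truth_spots.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(lattice$basis_lab),
                     file.path(outdir, "truth_basis.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(drift_df, file.path(outdir, "truth_drift.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(lattice$refl[, c("h", "k", "l", "d", "intensity")],
                     file.path(outdir, "truth_intensities.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(info = info,
       truth = list(spots = spots, basis_lab = lattice$basis_lab,
                    drift = drift_df,
                    ref_intensities =
                      lattice$refl[, c("h", "k", "l", "d", "intensity")],
                    orientation = lattice$orientation))
}
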