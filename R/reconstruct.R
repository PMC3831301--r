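## Reciprocal-space reconstruction.
##
## A spot at beam-centred detector position (x, y) corresponds to a point on
## the Ewald sphere (radius 1/lambda, passing through the origin, centre on
## the +z beam axis). Back-projection recovers that point; rotating it about
## the tilt axis by the frame's combined tilt places it at its fixed position
## in reciprocal space. Conventions (fixed, simulator and processor share
## them): 0-based pixels, x = column, y = row, right-handed lab frame with
## +z along the beam; positive combined tilt rotates points counterclockwise
## about the axis (cos phi, sin phi, 0) seen from the axis tip. An overall
## sign flip of the axis gives the enantiomorphic reconstruction, which
## rotation data cannot distinguish.

#' Back-project a detector position onto the Ewald sphere
#'
#' @param x,y beam-centred, shift-corrected detector coordinates in pixels
#'   (vectorized).
#' @param info [experiment_info()] object (wavelength and sampling).
#' @return n x 3 matrix of reciprocal-space positions (1/A) on the Ewald
#'   sphere: `gz = 1/lambda - sqrt(1/lambda^2 - gperp^2)`.
#' @export
back_project_spot <- function(x, y, info) {
  ppa <- info$pixels_per_inv_angstrom
  gx <- x / ppa
  gy <- y / ppa
  t2 <- gx^2 + gy^2
  r <- 1 / info$wavelength
  if (any(t2 >= r^2))
    stop("spot outside the Ewald sphere: g_perp >= 1/lambda")
  cbind(gx = gx, gy = gy, gz = r - sqrt(r^2 - t2))
}

#' Tilt axis
#'
#' @param azimuth azimuth in degrees, normalized to `[0, 180)` (the axis is
#'   a line; the rotation sense is fixed by convention).
#' @return object of class `tilt_axis`.
#' @export
tilt_axis <- function(azimuth) {
  structure(list(azimuth = azimuth %% 180), class = "tilt_axis")
}

#' Map 2D spots into 3D reciprocal space
#'
#' Back-projects every spot onto the Ewald sphere and rotates it about the
#' tilt axis by its frame's combined tilt. Frames with equal combined tilt
#' (overlap frames of the beam-tilt sweeps) are deduplicated, keeping the
#' first occurrence.
#'
#' @param spots data.frame with columns `frame`, `x`, `y` (beam-centred,
#'   shift-corrected pixels) and optionally intensity columns, which are
#'   carried through.
#' @param info [experiment_info()] object.
#' @param axis [tilt_axis()] or azimuth in degrees.
#' @return data.frame of class `spots3d`: input columns plus `gx, gy, gz`
#'   (1/A, rotated positions).
#' @export
map_to_3d <- function(spots, info, axis) {
  if (inherits(axis, "tilt_axis")) axis <- axis$azimuth
  ct <- round(info$frames$combined_tilt, 5)
  keep_frames <- which(!duplicated(ct))
  spots <- spots[spots$frame %in% keep_frames, , drop = FALSE]
  if (nrow(spots) == 0) {
    spots$gx <- spots$gy <- spots$gz <- numeric(0)
    return(spots)
  }
  sphere <- back_project_spot(spots$x, spots$y, info)
  theta <- info$frames$combined_tilt[spots$frame]
  g <- rotate_rows_about_azimuth(sphere, axis, theta)
  spots$gx <- g[, 1]; spots$gy <- g[, 2]; spots$gz <- g[, 3]
  class(spots) <- c("spots3d", "data.frame")
  spots
}

#' Refine the tilt-axis azimuth by a straightness scan
#'
#' With a wrong azimuth the reconstructed lattice rows appear bent, so the
#' clouds of short difference vectors between reconstructed spots smear out.
#' For each trial azimuth the spots are mapped to 3D and the mean covariance
#' trace of the three shortest difference-vector clusters is taken as the
#' score; the minimum over a coarse grid is refined on a fine grid.
#'
#' @param spots 2D spot table as for [map_to_3d()] (beam-centred pixels with
#'   a `frame` column; an intensity column is used to pick the strongest
#'   spots).
#' @param info [experiment_info()] object.
#' @param scan numeric(4): start, stop, coarse step, fine step in degrees
#'   (default `c(0, 180, 0.5, 0.1)`).
#' @param n_spots number of spots used for the scan (strongest spots within
#'   the low-resolution half of the data; default 1500).
#' @param diff_window length window (1/A) for difference vectors; `NULL`
#'   estimates it from the data at the first trial orientation.
#' @return [tilt_axis()] with attributes `score_curve` (data.frame
#'   `azimuth, score` for the coarse grid) and `fine_curve`.
#' @export
refine_tilt_axis <- function(spots, info, scan = c(0, 180, 0.5, 0.1),
                             n_spots = 1500, diff_window = NULL) {
  if (nrow(spots) < 100)
    warning("fewer than 100 spots: tilt-axis refinement has low confidence")
  tilt_span <- diff(range(info$frames$combined_tilt))
  if (tilt_span < 20)
    warning("tilt range below 20 degrees: axis refinement may be degenerate")
  ## Pre-merge spots into trial-independent "tracks" (frame-adjacent and
  ## close on the detector): the multi-frame rocking spread of one
  ## reflection would otherwise smear the difference-vector clusters at
  ## every trial azimuth and drown the bending signal.
  wcol <- intersect(c("intensity", "I", "integrated", "smoothed_peak",
                      "raw_peak"), names(spots))[1]
  w <- if (is.na(wcol)) rep(1, nrow(spots)) else pmax(spots[[wcol]], 1e-9)
  track <- link_tracks_2d(spots$frame, spots$x, spots$y, r2d = 6, gap = 2)
  sphere <- back_project_spot(spots$x, spots$y, info)
  theta <- info$frames$combined_tilt[spots$frame]
  wsum <- as.vector(rowsum(w, track))
  ## track selection: low-resolution half (dense lattice sampling), then the
  ## strongest n_spots tracks
  tr_r2d <- as.vector(rowsum(sqrt(spots$x^2 + spots$y^2) * w, track)) / wsum
  tr_int <- as.vector(rowsum(w, track))
  sel <- which(tr_r2d <= stats::quantile(tr_r2d, 0.5))
  if (length(sel) > n_spots)
    sel <- sel[order(-tr_int[sel])[seq_len(n_spots)]]
  score_at <- function(phi, win) {
    g <- rotate_rows_about_azimuth(sphere, phi, theta)
    pos <- rowsum(g * w, track) / wsum
    dv <- .short_diff_vectors_cpp(pos[sel, , drop = FALSE], win[1], win[2])
    cl <- three_shortest_clusters(dv, rel_eps = 0.3)
    if (is.null(cl)) return(Inf)
    ## mean covariance trace of the three shortest clusters, normalized by
    ## the fraction of difference vectors they capture: a bent lattice both
    ## inflates the clouds and depopulates them
    tr <- mean(vapply(cl, function(v) sum(diag(stats::cov(v))), 0))
    frac <- sum(vapply(cl, nrow, 0L)) / nrow(dv)
    tr / max(frac, 1e-6)
  }
  phi0 <- scan[1]
  if (is.null(diff_window)) {
    g0 <- rotate_rows_about_azimuth(sphere, phi0, theta)
    pos0 <- (rowsum(g0 * w, track) / wsum)[sel, , drop = FALSE]
    diff_window <- estimate_diff_window(pos0)
  }
  coarse <- seq(scan[1], scan[2], by = scan[3]) %% 180
  coarse <- coarse[!duplicated(round(coarse, 6))]
  cs <- vapply(coarse, score_at, 0, win = diff_window)
  best <- coarse[which.min(cs)]
  fine <- seq(best - scan[3], best + scan[3], by = scan[4])
  fs <- vapply(fine %% 180, score_at, 0, win = diff_window)
  ax <- tilt_axis(fine[which.min(fs)])
  attr(ax, "score_curve") <- data.frame(azimuth = coarse, score = cs)
  attr(ax, "fine_curve") <- data.frame(azimuth = fine %% 180, score = fs)
  ax
}

## Single-linkage grouping of spots into multi-frame tracks using only
## trial-independent information: frame adjacency (gap <= `gap` in recorded
## frame order) and 2D detector distance <= r2d. Returns integer group ids.
link_tracks_2d <- function(frame, x, y, r2d = 6, gap = 2) {
  n <- length(frame)
  frames <- sort(unique(frame))
  rank <- match(frame, frames)
  by_rank <- split(seq_len(n), rank)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_along(by_rank)) {
    for (dg in seq_len(gap)) {
      r2 <- r + dg
      if (r2 > length(by_rank)) break
      ia <- by_rank[[r]]; ib <- by_rank[[r2]]
      d2 <- outer(x[ia], x[ib], "-")^2 + outer(y[ia], y[ib], "-")^2
      hit <- which(d2 <= r2d^2, arr.ind = TRUE)
      for (m in seq_len(nrow(hit))) {
        ra <- find(ia[hit[m, 1]]); rb <- find(ib[hit[m, 2]])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

## Data-driven [min, max] length window for difference vectors: beyond the
## multi-frame self-distance (near zero) and up to ~2 shortest spacings.
estimate_diff_window <- function(g, self_dist = 0.012) {
  dv <- .short_diff_vectors_cpp(g, self_dist, 0.35)
  if (nrow(dv) < 10) return(c(self_dist, 0.35))
  len <- sqrt(rowSums(dv^2))
  h <- stats::density(len, bw = 0.002, from = self_dist, to = 0.35, n = 256)
  ## first prominent mode = shortest lattice spacing
  pk <- which(diff(sign(diff(h$y))) == -2) + 1
  pk <- pk[h$y[pk] > 0.1 * max(h$y)]
  d1 <- if (length(pk)) h$x[pk[1]] else stats::median(len)
  c(max(self_dist, 0.5 * d1), 2.2 * d1)
}

#' Cut a section through the reconstructed reciprocal lattice
#'
#' Selects the spots whose fractional coordinate along one reciprocal axis
#' (or along an arbitrary plane normal) lies within `offset +/- thickness/2`,
#' e.g. the hk0 layer (`axis_index = 3, offset = 0`) or an h1l-type layer
#' that does not pass through 000.
#'
#' @param spots3d data.frame from [map_to_3d()] (columns `gx, gy, gz`).
#' @param basis 3x3 reciprocal basis matrix (columns a*, b*, c*) for indexed
#'   cuts, or `NULL` with `normal` given.
#' @param axis_index which fractional index defines the layer (1 = h,
#'   2 = k, 3 = l) when `basis` is used.
#' @param offset integer layer index.
#' @param thickness slab thickness in fractional units (default 0.5).
#' @param normal plane normal (lab frame) used with `spacing` when no basis
#'   is available: the fractional coordinate is `(g . n) / spacing`.
#' @param spacing layer spacing along `normal` in 1/A.
#' @return the subset of `spots3d` lying in the slab.
#' @export
cut_section <- function(spots3d, basis = NULL, axis_index = 3, offset = 0,
                        thickness = 0.5, normal = NULL, spacing = NULL) {
  stopifnot(thickness > 0)
  if (!is.null(basis)) {
    frac <- solve(basis, t(as.matrix(spots3d[, c("gx", "gy", "gz")])))
    coord <- frac[axis_index, ]
  } else {
    stopifnot(!is.null(normal), !is.null(spacing))
    n <- normal / sqrt(sum(normal^2))
    coord <- (spots3d$gx * n[1] + spots3d$gy * n[2] + spots3d$gz * n[3]) /
      spacing
  }
  spots3d[abs(coord - offset) <= thickness / 2, , drop = FALSE]
}
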