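## Reflection merging, 3D integration, basis determination and indexing.
##
## Spots from consecutive frames that sample the same reflection are merged
## by single-linkage grouping (close in 2D on the detector AND in 3D in
## reciprocal space AND within a small frame gap). Basis vectors come from
## density clustering of the short difference vectors between merged
## reflections; indexing walks outward in resolution re-anchoring on already
## indexed neighbours so that a slightly bent lattice still indexes.

## ---- merging -------------------------------------------------------------

#' Merge multi-frame spots into reflections
#'
#' Two spots link when their frame gap (in recorded-frame order) is at most
#' `max_frame_gap`, their 3D distance is at most `merge_3d_radius` and their
#' 2D detector distance is at most `merge_2d_radius`; reflections are the
#' connected components of this relation.
#'
#' @param spots3d data.frame from [map_to_3d()] (columns `frame, x, y,
#'   gx, gy, gz` plus intensity columns).
#' @param merge_2d_radius link radius on the detector in pixels (default 6).
#' @param merge_3d_radius link radius in reciprocal space in 1/A (default
#'   0.0075, about 2.5 rocking half-widths of the reference simulation).
#' @param max_frame_gap maximum frame gap for a link (default 2).
#' @param intensity_col column used as the per-spot intensity I_i (default
#'   the first of `raw_peak`, `smoothed_peak`, `integrated`, `intensity`
#'   present).
#' @return data.frame of class `reflections`: `gx, gy, gz`
#'   (intensity-weighted mean position), `I_max`, `I_3d` (3D-integrated
#'   intensity, see [integrate_reflection_3d()]), `i3d_fallback` (TRUE when
#'   a single-member reflection fell back to `I_max`), `n` (member count),
#'   `frame_of_max`, `x, y` (detector position of the strongest member),
#'   `saturated` (any member saturated), `d` (Angstrom). The input spots
#'   with their reflection id are attached as attribute `members`.
#' @export
merge_spots <- function(spots3d, merge_2d_radius = 6, merge_3d_radius = 0.0075,
                        max_frame_gap = 2, intensity_col = NULL) {
  stopifnot(merge_2d_radius > 0, merge_3d_radius > 0, max_frame_gap >= 0,
            nrow(spots3d) >= 1)
  if (is.null(intensity_col))
    intensity_col <- intersect(c("raw_peak", "smoothed_peak", "integrated",
                                 "intensity"), names(spots3d))[1]
  stopifnot(!is.na(intensity_col), intensity_col %in% names(spots3d))
  n <- nrow(spots3d)
  frames <- sort(unique(spots3d$frame))
  rank <- match(spots3d$frame, frames)
  by_rank <- split(seq_len(n), rank)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  g <- as.matrix(spots3d[, c("gx", "gy", "gz")])
  xy <- as.matrix(spots3d[, c("x", "y")])
  for (r in seq_along(by_rank)) {
    for (gap in seq_len(max_frame_gap)) {
      r2 <- r + gap
      if (r2 > length(by_rank)) break
      ia <- by_rank[[r]]; ib <- by_rank[[r2]]
      d3 <- outer(g[ia, 1], g[ib, 1], "-")^2 +
            outer(g[ia, 2], g[ib, 2], "-")^2 +
            outer(g[ia, 3], g[ib, 3], "-")^2
      d2 <- outer(xy[ia, 1], xy[ib, 1], "-")^2 +
            outer(xy[ia, 2], xy[ib, 2], "-")^2
      hit <- which(d3 <= merge_3d_radius^2 & d2 <= merge_2d_radius^2,
                   arr.ind = TRUE)
      for (m in seq_len(nrow(hit))) {
        ra <- find(ia[hit[m, 1]]); rb <- find(ib[hit[m, 2]])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  id <- match(root, unique(root))
  I <- spots3d[[intensity_col]]
  sat <- if ("saturated" %in% names(spots3d)) spots3d$saturated else
    rep(FALSE, n)
  ## aggregate in (id, frame) order so Eq.-1 integration sees members sorted
  o <- order(id, spots3d$frame)
  ids <- id[o]; Is <- I[o]; gs <- g[o, , drop = FALSE]
  w <- pmax(Is, 0)
  wsum <- rowsum(w, ids)
  wsum[wsum == 0] <- NA  # all-nonpositive group: fall back to plain mean
  gw <- rowsum(gs * w, ids) / as.vector(wsum)
  gm <- rowsum(gs, ids) / as.vector(rowsum(rep(1, length(ids)), ids))
  bad <- !is.finite(gw[, 1])
  gw[bad, ] <- gm[bad, ]
  ## Eq.-1 integration: sum_{i>=2} I_i |K_i - K_{i-1}| within each group
  same <- c(FALSE, ids[-1] == ids[-length(ids)])
  dk <- c(0, sqrt(rowSums((gs[-1, , drop = FALSE] -
                           gs[-length(ids), , drop = FALSE])^2)))
  contrib <- ifelse(same, Is * dk, 0)
  I3d <- as.vector(rowsum(contrib, ids))
  nmem <- as.vector(rowsum(rep(1L, length(ids)), ids))
  ## strongest member per group (ties: earliest frame, then lowest y, x)
  o2 <- order(id, -I, spots3d$frame, spots3d$y, spots3d$x)
  topi <- o2[!duplicated(id[o2])]
  top <- data.frame(id = id[topi], I_max = I[topi],
                    frame_of_max = spots3d$frame[topi],
                    x = spots3d$x[topi], y = spots3d$y[topi])
  top <- top[order(top$id), ]
  fallback <- nmem == 1
  I3d[fallback] <- top$I_max[fallback]
  glen <- sqrt(rowSums(gw^2))
  out <- data.frame(gx = gw[, 1], gy = gw[, 2], gz = gw[, 3],
                    I_max = top$I_max, I_3d = I3d,
                    i3d_fallback = fallback, n = nmem,
                    frame_of_max = top$frame_of_max, x = top$x, y = top$y,
                    saturated = as.vector(rowsum(sat[o] * 1L, ids)) > 0,
                    d = 1 / glen)
  class(out) <- c("reflections", "data.frame")
  members <- spots3d
  members$refl <- id
  attr(out, "members") <- members
  attr(out, "intensity_col") <- intensity_col
  out
}

#' 3D-integrated intensity of one reflection
#'
#' Integrates the per-frame spot intensities over the reciprocal difference
#' vectors between neighbouring members:
#' `I = sum_{i=2..n} I_i * |K_i - K_{i-1}|`, members sorted by frame. A
#' single-member reflection falls back to its maximum intensity with
#' `fallback = TRUE`.
#'
#' @param members data.frame with columns `frame`, `gx, gy, gz` and the
#'   intensity column `I` (or named by `intensity_col`).
#' @param intensity_col name of the intensity column (default `"I"`).
#' @return list with `I_3d` and `fallback`.
#' @export
integrate_reflection_3d <- function(members, intensity_col = "I") {
  stopifnot(nrow(members) >= 1, intensity_col %in% names(members))
  m <- members[order(members$frame), , drop = FALSE]
  I <- m[[intensity_col]]
  if (nrow(m) == 1) return(list(I_3d = I[1], fallback = TRUE))
  K <- as.matrix(m[, c("gx", "gy", "gz")])
  dk <- sqrt(rowSums((K[-1, , drop = FALSE] -
                      K[-nrow(K), , drop = FALSE])^2))
  list(I_3d = sum(I[-1] * dk), fallback = FALSE)
}

## ---- difference-vector clustering ----------------------------------------

## Greedy "three shortest clusters" used by the tilt-axis straightness score:
## repeatedly seed at the shortest unassigned difference vector and collect
## everything within a relative radius, two centroid passes. Deterministic.
three_shortest_clusters <- function(dv, rel_eps = 0.22, min_pts = 5,
                                    n_clusters = 3) {
  if (nrow(dv) < n_clusters * min_pts) return(NULL)
  len <- sqrt(rowSums(dv^2))
  ord <- order(len)
  assigned <- rep(FALSE, nrow(dv))
  clusters <- list()
  for (i in ord) {
    if (assigned[i]) next
    if (length(clusters) >= n_clusters) break
    eps <- rel_eps * len[i]
    d2 <- (dv[, 1] - dv[i, 1])^2 + (dv[, 2] - dv[i, 2])^2 +
          (dv[, 3] - dv[i, 3])^2
    mem <- !assigned & d2 <= eps^2
    cen <- colMeans(dv[mem, , drop = FALSE])
    d2 <- (dv[, 1] - cen[1])^2 + (dv[, 2] - cen[2])^2 +
          (dv[, 3] - cen[3])^2
    mem <- !assigned & d2 <= eps^2
    assigned[mem] <- TRUE
    assigned[i] <- TRUE
    if (sum(mem) >= min_pts)
      clusters[[length(clusters) + 1]] <- dv[mem, , drop = FALSE]
  }
  if (length(clusters) < n_clusters) return(NULL)
  clusters
}

#' Find the reciprocal basis by difference-vector clustering
#'
#' All short difference vectors between merged reflections are
#' sign-canonicalized and density-clustered (DBSCAN); the cluster centroids,
#' sorted by length, are scanned for the three shortest noncoplanar vectors,
#' which after a Buerger-style shortening pass become a*, b*, c*.
#'
#' @param reflections [merge_spots()] output, or any data.frame/matrix with
#'   `gx, gy, gz` columns.
#' @param cluster_eps DBSCAN radius in 1/A; default 0.15 x the shortest
#'   spacing estimated from the length histogram.
#' @param min_pts DBSCAN core-point threshold; default
#'   `max(5, 0.2%% of difference vectors)`.
#' @param max_diff_len keep difference vectors up to this length (1/A);
#'   default 3 x the estimated shortest spacing.
#' @param n_use at most this many lowest-resolution reflections enter the
#'   O(n^2) difference-vector computation (default 2000).
#' @param max_vectors cap on clustered difference vectors (deterministic
#'   stride subsampling beyond it; default 30000).
#' @return 3x3 matrix of class `reciprocal_basis`, columns a*, b*, c* (1/A),
#'   right-handed, sorted by length; attribute `diagnostics` carries the
#'   cluster table and the parameters actually used.
#' @export
find_reciprocal_basis <- function(reflections, cluster_eps = NULL,
                                  min_pts = NULL, max_diff_len = NULL,
                                  n_use = 2000, max_vectors = 30000) {
  g <- as.matrix(as.data.frame(reflections)[, c("gx", "gy", "gz")])
  if (nrow(g) < 10) stop("too few reflections for basis determination")
  glen <- sqrt(rowSums(g^2))
  if (nrow(g) > n_use) g <- g[order(glen)[seq_len(n_use)], , drop = FALSE]
  ## estimate the shortest lattice spacing from a provisional vector set
  dv0 <- .short_diff_vectors_cpp(g, 1e-6, 0.35)
  if (nrow(dv0) < 30) stop("too few difference vectors; increase n_use")
  len0 <- sqrt(rowSums(dv0^2))
  dens <- stats::density(len0, bw = 0.002, from = 0, to = 0.35, n = 512)
  pk <- which(diff(sign(diff(dens$y))) == -2) + 1
  pk <- pk[dens$y[pk] > 0.1 * max(dens$y)]
  d1 <- if (length(pk)) dens$x[pk[1]] else stats::median(len0)
  if (is.null(max_diff_len)) max_diff_len <- 3 * d1
  if (is.null(cluster_eps)) cluster_eps <- 0.15 * d1
  dv <- .short_diff_vectors_cpp(g, 0.35 * d1, max_diff_len)
  if (nrow(dv) > max_vectors)
    dv <- dv[seq(1, nrow(dv), length.out = max_vectors), , drop = FALSE]
  if (is.null(min_pts)) min_pts <- max(5, ceiling(0.002 * nrow(dv)))
  lab <- .dbscan_cpp(dv, cluster_eps, as.integer(min_pts))
  if (!any(lab > 0))
    stop("difference-vector clustering found no clusters; ",
         "try a larger cluster_eps or max_diff_len")
  cl <- split(seq_len(nrow(dv)), lab)
  cl[["0"]] <- NULL
  cent <- t(vapply(cl, function(i) colMeans(dv[i, , drop = FALSE]),
                   numeric(3)))
  sizes <- lengths(cl)
  ## sign canonicalization is unstable when the two leading components of a
  ## direction have near-equal magnitude: one physical cluster then shows up
  ## twice, as v and a near-image of -v. Merge such flip images (and any
  ## near-duplicates) before ranking by length.
  merged <- merge_flip_images(cent, sizes, tol = 2.5 * cluster_eps)
  cent <- merged$cent; sizes <- merged$sizes
  clen <- sqrt(rowSums(cent^2))
  ord <- order(clen)
  cent <- cent[ord, , drop = FALSE]; sizes <- sizes[ord]; clen <- clen[ord]
  diag_tab <- data.frame(length = clen, n = sizes, cx = cent[, 1],
                         cy = cent[, 2], cz = cent[, 3])
  ## three shortest noncoplanar centroids
  pick <- pick_noncoplanar(cent)
  if (is.null(pick))
    stop("no three noncoplanar difference-vector clusters ",
         sprintf("(found %d clusters, shortest %.4f 1/A); ", nrow(cent),
                 if (nrow(cent)) clen[1] else NA),
         "try a larger max_diff_len")
  B <- t(cent[pick, , drop = FALSE])
  B <- buerger_reduce(B)
  ## canonical presentation: sorted by length, right-handed
  B <- B[, order(sqrt(colSums(B^2))), drop = FALSE]
  if (det(B) < 0) B[, 3] <- -B[, 3]
  structure(B, class = c("reciprocal_basis", "matrix", "array"),
            diagnostics = list(clusters = diag_tab, d1 = d1,
                               cluster_eps = cluster_eps, min_pts = min_pts,
                               max_diff_len = max_diff_len,
                               n_vectors = nrow(dv), picked = pick))
}

## Merge cluster centroids that are images of each other under sign flip
## (or near-duplicates): size-weighted mean, iterated to a fixpoint.
merge_flip_images <- function(cent, sizes, tol) {
  repeat {
    k <- nrow(cent)
    if (k < 2) break
    done <- TRUE
    for (i in seq_len(k - 1)) {
      dminus <- sqrt(rowSums((cent[-seq_len(i), , drop = FALSE] -
                              matrix(cent[i, ], k - i, 3, byrow = TRUE))^2))
      dplus <- sqrt(rowSums((cent[-seq_len(i), , drop = FALSE] +
                             matrix(cent[i, ], k - i, 3, byrow = TRUE))^2))
      hit <- which(pmin(dminus, dplus) < tol)
      if (length(hit)) {
        j <- i + hit[1]
        cj <- if (dminus[hit[1]] <= dplus[hit[1]]) cent[j, ] else -cent[j, ]
        w <- sizes[c(i, j)]
        cent[i, ] <- (w[1] * cent[i, ] + w[2] * cj) / sum(w)
        sizes[i] <- sum(w)
        cent <- cent[-j, , drop = FALSE]
        sizes <- sizes[-j]
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  list(cent = cent, sizes = sizes)
}

## Indices of the three shortest rows of `cent` that are mutually
## noncoplanar (|det| > 0.01 * product of lengths); NULL when impossible.
pick_noncoplanar <- function(cent) {
  nclust <- nrow(cent)
  if (nclust < 3) return(NULL)
  len <- sqrt(rowSums(cent^2))
  i1 <- 1
  for (i2 in seq_len(nclust)[-i1]) {
    cr <- c(cent[i1, 2] * cent[i2, 3] - cent[i1, 3] * cent[i2, 2],
            cent[i1, 3] * cent[i2, 1] - cent[i1, 1] * cent[i2, 3],
            cent[i1, 1] * cent[i2, 2] - cent[i1, 2] * cent[i2, 1])
    if (sqrt(sum(cr^2)) <= 0.01 * len[i1] * len[i2]) next
    for (i3 in seq_len(nclust)[-c(i1, i2)]) {
      dt <- abs(sum(cr * cent[i3, ]))
      if (dt > 0.01 * len[i1] * len[i2] * len[i3])
        return(c(i1, i2, i3))
    }
    break  # i2 fixed as the first noncollinear partner; i3 exhausted
  }
  ## retry allowing later i2 choices
  for (i2 in seq_len(nclust)[-i1]) {
    for (i3 in seq_len(nclust)) {
      if (i3 == i1 || i3 == i2) next
      M <- rbind(cent[i1, ], cent[i2, ], cent[i3, ])
      if (abs(det(M)) > 0.01 * len[i1] * len[i2] * len[i3])
        return(c(i1, i2, i3))
    }
  }
  NULL
}

## Buerger-style shortest-vector pass: replace any basis vector by
## combinations v_i +/- v_j (and +/- v_j +/- v_k) that shorten it, iterate
## to a fixpoint.
buerger_reduce <- function(B, max_iter = 50) {
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (i in 1:3) {
      others <- setdiff(1:3, i)
      combos <- expand.grid(a = -1:1, b = -1:1)
      best <- B[, i]; bl <- sum(best^2)
      for (r in seq_len(nrow(combos))) {
        cand <- B[, i] + combos$a[r] * B[, others[1]] +
          combos$b[r] * B[, others[2]]
        if (sum(cand^2) < bl - 1e-12 * bl) {
          best <- cand; bl <- sum(cand^2); changed <- TRUE
        }
      }
      B[, i] <- best
    }
    if (!changed) break
  }
  B
}

#' Real-space unit cell from a reciprocal basis
#'
#' @param basis 3x3 reciprocal basis matrix, columns a*, b*, c* (1/A).
#' @param transform optional 3x3 integer matrix `T` with `|det(T)| >= 1`
#'   re-expressing the basis before conversion:
#'   `a*' = T[1,1] a* + T[1,2] b* + T[1,3] c*`, etc.
#' @return [unit_cell()] with lengths in Angstrom and angles in degrees; the
#'   real-space vectors are the rows of the inverse of the reciprocal-basis
#'   matrix.
#' @export
cell_parameters_from_basis <- function(basis, transform = NULL) {
  B <- unclass(basis)
  stopifnot(is.matrix(B), all(dim(B) == c(3, 3)))
  if (!is.null(transform)) {
    stopifnot(all(dim(transform) == c(3, 3)),
              abs(det(transform)) >= 1 - 1e-9)
    B <- B %*% t(transform)
  }
  if (abs(det(B)) < 1e-12) stop("singular reciprocal basis")
  A <- t(solve(B))  # columns = real-space a, b, c
  cell_from_real_matrix(A)
}

## ---- indexing ------------------------------------------------------------

#' Indexing parameters
#'
#' @param threshold per-axis acceptance threshold on `|frac - round(frac)|`;
#'   scalar or length-3 (default 0.1, must be in (0, 0.5)).
#' @param neighbor_radius radius (1/A) within which already indexed
#'   reflections may serve as the local origin; `NULL` defaults to 2.5 x the
#'   longest basis vector.
#' @param resolution_ordered process reflections in ascending `|g|`
#'   (default TRUE; FALSE indexes in input order, for diagnostics only).
#' @return object of class `index_params`.
#' @export
index_params <- function(threshold = 0.1, neighbor_radius = NULL,
                         resolution_ordered = TRUE) {
  stopifnot(all(threshold > 0), all(threshold < 0.5),
            length(threshold) %in% c(1, 3))
  structure(list(threshold = rep(threshold, length.out = 3),
                 neighbor_radius = neighbor_radius,
                 resolution_ordered = resolution_ordered),
            class = "index_params")
}

#' Adaptively index merged reflections
#'
#' Reflections are processed from low to high resolution. Each one is
#' decomposed relative to its nearest already accepted neighbour (the origin
#' 000 is the first neighbour): fractional indices are the neighbour's
#' integer indices plus `B^-1 (g - g_neighbour)`. A reflection is accepted
#' when every per-axis deviation from an integer is at most the threshold;
#' rejected reflections are kept with `accepted = FALSE`. Re-anchoring on
#' local neighbours makes the scheme tolerant to lattice bending from a
#' slightly wrong tilt axis.
#'
#' @param reflections [merge_spots()] output (or data.frame with
#'   `gx, gy, gz`).
#' @param basis [find_reciprocal_basis()] output or 3x3 matrix.
#' @param params [index_params()] object.
#' @return the input with columns `h_frac, k_frac, l_frac` (fractional
#'   indices), `h, k, l` (rounded), `deviation` (max per-axis `|frac -
#'   round|`) and `accepted`.
#' @export
index_reflections <- function(reflections, basis, params = index_params()) {
  B <- unclass(basis)
  Binv <- solve(B)
  refl <- as.data.frame(reflections)
  n <- nrow(refl)
  g <- as.matrix(refl[, c("gx", "gy", "gz")])
  nb_radius <- params$neighbor_radius
  if (is.null(nb_radius)) nb_radius <- 2.5 * max(sqrt(colSums(B^2)))
  ord <- if (params$resolution_ordered)
    order(rowSums(g^2)) else seq_len(n)
  ## accepted anchor store: origin first
  anchor_g <- matrix(0, n + 1, 3)
  anchor_hkl <- matrix(0, n + 1, 3)
  n_anchor <- 1L
  frac <- matrix(NA_real_, n, 3)
  hkl <- matrix(NA_integer_, n, 3)
  dev <- numeric(n)
  acc <- logical(n)
  thr <- params$threshold
  for (i in ord) {
    ag <- anchor_g[seq_len(n_anchor), , drop = FALSE]
    d2 <- (ag[, 1] - g[i, 1])^2 + (ag[, 2] - g[i, 2])^2 +
          (ag[, 3] - g[i, 3])^2
    cand <- which(d2 <= nb_radius^2)
    nb <- if (length(cand) == 0) 1L else cand[which.min(d2[cand])]
    f <- anchor_hkl[nb, ] + as.vector(Binv %*% (g[i, ] - anchor_g[nb, ]))
    r <- round(f)
    e <- abs(f - r)
    frac[i, ] <- f
    hkl[i, ] <- as.integer(r)
    dev[i] <- max(e)
    if (all(e <= thr)) {
      acc[i] <- TRUE
      n_anchor <- n_anchor + 1L
      anchor_g[n_anchor, ] <- g[i, ]
      anchor_hkl[n_anchor, ] <- r
    }
  }
  refl$h_frac <- frac[, 1]; refl$k_frac <- frac[, 2]; refl$l_frac <- frac[, 3]
  refl$h <- hkl[, 1]; refl$k <- hkl[, 2]; refl$l <- hkl[, 3]
  refl$deviation <- dev
  refl$accepted <- acc
  class(refl) <- c("indexed_reflections", "data.frame")
  refl
}

#' Least-squares refinement of the reciprocal basis
#'
#' The difference-vector clustering gives basis vectors limited by the
#' cluster-centroid precision. Once reflections carry integer indices, the
#' basis is overdetermined by thousands of equations `g = B (h,k,l)` and a
#' linear least-squares fit over the accepted reflections sharpens it by an
#' order of magnitude (this is the standard cell-refinement step after
#' indexing).
#'
#' @param indexed [index_reflections()] output.
#' @param min_n minimum number of accepted reflections required (default
#'   20).
#' @return refined 3x3 `reciprocal_basis` matrix.
#' @export
refine_basis <- function(indexed, min_n = 20) {
  df <- as.data.frame(indexed)
  acc <- df[df$accepted, , drop = FALSE]
  if (nrow(acc) < min_n)
    stop("too few accepted reflections for basis refinement")
  H <- cbind(acc$h, acc$k, acc$l)
  G <- as.matrix(acc[, c("gx", "gy", "gz")])
  HtH <- crossprod(H)
  if (abs(det(HtH)) < 1e-9) stop("indexed reflections are degenerate")
  B <- t(solve(HtH, crossprod(H, G)))
  dimnames(B) <- NULL
  structure(B, class = c("reciprocal_basis", "matrix", "array"))
}

## ---- systematic absences -------------------------------------------------

#' Reflection statistics for systematic-absence screening
#'
#' Tabulates, for the standard centring, glide and screw-axis extinction
#' classes, the number of (accepted) reflections in the would-be-absent
#' subset and their mean intensity and mean I/sigma with `sigma = sqrt(I)`.
#'
#' @param indexed [index_reflections()] output.
#' @param intensity_col intensity column (default `"I_max"`, falling back to
#'   `"intensity"` or `"I"`).
#' @param accepted_only use accepted reflections only (default TRUE).
#' @return data.frame with columns `class, n, mean_I, mean_I_over_sigma`
#'   (NA-safe for empty classes).
#' @export
absence_statistics <- function(indexed, intensity_col = NULL,
                               accepted_only = TRUE) {
  df <- as.data.frame(indexed)
  if (is.null(intensity_col))
    intensity_col <- intersect(c("I_max", "intensity", "I", "I_3d"),
                               names(df))[1]
  stopifnot(!is.na(intensity_col))
  if (accepted_only && "accepted" %in% names(df))
    df <- df[df$accepted, , drop = FALSE]
  h <- df$h; k <- df$k; l <- df$l
  I <- df[[intensity_col]]
  odd <- function(x) x %% 2 != 0
  classes <- list(
    "hkl: h+k+l odd (I centring)" = odd(h + k + l),
    "hkl: h+k odd (C centring)"   = odd(h + k),
    "hkl: h+l odd (B centring)"   = odd(h + l),
    "hkl: k+l odd (A centring)"   = odd(k + l),
    "h0l: h odd (a glide)"        = k == 0 & odd(h),
    "h0l: l odd (c glide)"        = k == 0 & odd(l),
    "h0l: h+l odd (n glide)"      = k == 0 & odd(h + l),
    "0kl: k odd (b glide)"        = h == 0 & odd(k),
    "0kl: l odd (c glide)"        = h == 0 & odd(l),
    "0kl: k+l odd (n glide)"      = h == 0 & odd(k + l),
    "hk0: h odd (a glide)"        = l == 0 & odd(h),
    "hk0: k odd (b glide)"        = l == 0 & odd(k),
    "hk0: h+k odd (n glide)"      = l == 0 & odd(h + k),
    "h00: h odd (2_1 axis)"       = k == 0 & l == 0 & odd(h),
    "0k0: k odd (2_1 axis)"       = h == 0 & l == 0 & odd(k),
    "00l: l odd (2_1 axis)"       = h == 0 & k == 0 & odd(l))
  rows <- lapply(names(classes), function(nm) {
    sel <- classes[[nm]]
    Ii <- I[sel]
    if (length(Ii) == 0)
      return(data.frame(class = nm, n = 0L, mean_I = NA_real_,
                        mean_I_over_sigma = NA_real_))
    sig <- sqrt(pmax(Ii, 0))
    ios <- Ii[sig > 0] / sig[sig > 0]
    data.frame(class = nm, n = length(Ii), mean_I = mean(Ii),
               mean_I_over_sigma = if (length(ios)) mean(ios) else NA_real_)
  })
  do.call(rbind, rows)
}
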