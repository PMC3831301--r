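## Small geometry helpers shared by the simulator and the reconstruction.
## Angles cross the API in degrees and are converted to radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta_deg` degrees about the unit axis `u`
#' (counterclockwise when viewed from the axis tip, right-handed frame).
#'
#' @param u numeric(3) axis (normalized internally).
#' @param theta_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(u, theta_deg) {
  u <- u / sqrt(sum(u^2))
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
}

## Vectorized Rodrigues rotation of the rows of P (n x 3) by per-row angles
## theta_deg about the in-plane axis u = (cos phi, sin phi, 0).
rotate_rows_about_azimuth <- function(P, phi_deg, theta_deg) {
  phi <- deg2rad(phi_deg)
  u <- c(cos(phi), sin(phi), 0)
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  udotp <- P[, 1] * u[1] + P[, 2] * u[2] + P[, 3] * u[3]
  ## u x p
  cx <- u[2] * P[, 3] - u[3] * P[, 2]
  cy <- u[3] * P[, 1] - u[1] * P[, 3]
  cz <- u[1] * P[, 2] - u[2] * P[, 1]
  cbind(P[, 1] * ct + cx * st + u[1] * udotp * (1 - ct),
        P[, 2] * ct + cy * st + u[2] * udotp * (1 - ct),
        P[, 3] * ct + cz * st + u[3] * udotp * (1 - ct))
}

#' Unit cell
#'
#' Construct a unit cell from lengths (Angstrom) and angles (degrees).
#'
#' @param a,b,c axial lengths in Angstrom, all positive.
#' @param alpha,beta,gamma interaxial angles in degrees, each in (0, 180).
#' @return object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`.
#' @examples
#' unit_cell(20.02, 20.25, 13.35, 90, 90.74, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  ## metric tensor must be positive definite (triangle condition on angles)
  A <- real_space_matrix(cell)
  G <- crossprod(A)
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("degenerate cell: metric tensor not positive definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

## Real-space basis matrix, columns a, b, c (standard PDB-style frame:
## a along x, b in the xy plane).
real_space_matrix <- function(cell) {
  al <- deg2rad(cell$alpha); be <- deg2rad(cell$beta); ga <- deg2rad(cell$gamma)
  v <- sqrt(max(0, 1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                  2 * cos(al) * cos(be) * cos(ga)))
  if (v <= 0) stop("degenerate cell: angles violate the triangle condition")
  a <- c(cell$a, 0, 0)
  b <- c(cell$b * cos(ga), cell$b * sin(ga), 0)
  cc <- c(cell$c * cos(be),
          cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
          cell$c * v / sin(ga))
  cbind(a, b, cc, deparse.level = 0)
}

## Reciprocal basis matrix (columns a*, b*, c*, crystallographic 1/d
## convention without 2*pi): B = t(solve(A)).
reciprocal_matrix <- function(cell) {
  t(solve(real_space_matrix(cell)))
}

## Cell parameters from a real-space basis matrix (columns a, b, c).
cell_from_real_matrix <- function(A) {
  dimnames(A) <- NULL
  len <- sqrt(colSums(A^2))
  ang <- function(i, j) rad2deg(acos(sum(A[, i] * A[, j]) / (len[i] * len[j])))
  unit_cell(len[1], len[2], len[3], ang(2, 3), ang(1, 3), ang(1, 2))
}
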