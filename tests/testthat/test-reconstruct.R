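ref_info <- function(ppa = 280, wavelength = 0.0251) {
  frames <- data.frame(filename = "f.mrc", goniometer_tilt = 0,
                       beam_tilt = 0, combined_tilt = 0)
  experiment_info(wavelength, ppa, 48.5, frames)
}

test_that("back-projection satisfies the Ewald-sphere equation", {
  info <- ref_info()
  ## direct beam maps to the origin
  expect_equal(unname(back_project_spot(0, 0, info)[1, ]), c(0, 0, 0))
  ## closed-form check at g_perp = 1 along x (x = ppa px)
  p <- back_project_spot(280, 0, info)
  r <- 1 / 0.0251
  expect_equal(unname(p[1, "gz"]), r - sqrt(r^2 - 1), tolerance = 1e-12)
  expect_equal(unname(p[1, "gz"]), 0.012551, tolerance = 1e-4)
  ## sphere residual < 1e-10 relative for random positions
  set.seed(8)
  x <- runif(200, -250, 250); y <- runif(200, -250, 250)
  q <- back_project_spot(x, y, info)
  res <- abs(sqrt(q[, 1]^2 + q[, 2]^2 + (q[, 3] - r)^2) - r) / r
  expect_lt(max(res), 1e-10)
  ## out-of-sphere input is rejected
  expect_error(back_project_spot(1 / 0.0251 * 280, 0, info), "Ewald")
})

test_that("rotation into 3D follows the stated sense and preserves norms", {
  frames <- data.frame(filename = c("a", "b", "c"),
                       goniometer_tilt = c(0, 45, 90), beam_tilt = 0,
                       combined_tilt = c(0, 45, 90))
  info <- experiment_info(0.0251, 100, 0, frames)
  ## tilt 0: identity
  s0 <- map_to_3d(data.frame(frame = 1, x = 30, y = 40), info, tilt_axis(0))
  bp <- back_project_spot(30, 40, info)
  expect_equal(c(s0$gx, s0$gy, s0$gz), unname(bp[1, ]), tolerance = 1e-12)
  ## axis +x, tilt 90 deg: (0, gy, ~0) -> (0, ~0, gy)
  s90 <- map_to_3d(data.frame(frame = 3, x = 0, y = 40), info, tilt_axis(0))
  gy <- 40 / 100
  expect_equal(s90$gz, gy, tolerance = 1e-4)
  expect_equal(s90$gx, 0, tolerance = 1e-12)
  ## norm preservation to machine precision
  set.seed(3)
  sp <- data.frame(frame = sample(1:3, 100, TRUE),
                   x = runif(100, -80, 80), y = runif(100, -80, 80))
  s <- map_to_3d(sp, info, tilt_axis(37.3))
  n3 <- sqrt(s$gx^2 + s$gy^2 + s$gz^2)
  n0 <- sqrt(rowSums(back_project_spot(sp$x, sp$y, info)^2))
  expect_equal(n3, n0, tolerance = 1e-14)
})

test_that("overlap frames are deduplicated keeping the first occurrence", {
  frames <- data.frame(filename = c("a", "b", "c"),
                       goniometer_tilt = c(0, 0, 2),
                       beam_tilt = c(0, 2, 0),
                       combined_tilt = c(0, 2, 2))
  info <- experiment_info(0.0251, 100, 0, frames)
  sp <- data.frame(frame = c(1, 2, 3), x = c(10, 20, 30), y = 0)
  s <- map_to_3d(sp, info, tilt_axis(0))
  expect_equal(s$frame, c(1, 2))   # frame 3 duplicates combined tilt 2
  expect_equal(s$x, c(10, 20))
})

test_that("back-projection inverts the simulator projection exactly", {
  ## geometric inverse-pair oracle on noiseless continuous positions
  cfg <- small_noiseless_config()
  lat <- red3d:::sim_lattice(cfg)
  sched <- build_tilt_schedule(cfg$schedule)
  frames <- data.frame(filename = sprintf("f%d.mrc", seq_len(nrow(sched))),
                       goniometer_tilt = sched$goniometer_tilt,
                       beam_tilt = sched$beam_tilt,
                       combined_tilt = sched$combined_tilt)
  info <- experiment_info(cfg$wavelength, cfg$pixels_per_inv_angstrom,
                          cfg$tilt_axis_azimuth_true, frames,
                          cfg$detector_shape, cfg$bit_depth)
  worst <- 0
  for (fr in c(5, 60, 120, 180)) {
    proj <- frame_projection(cfg, sched$combined_tilt[fr], lat)
    if (nrow(proj) == 0) next
    sp <- data.frame(frame = fr, x = proj$x, y = proj$y)
    rec <- map_to_3d(sp, info, tilt_axis(48.5))
    err <- sqrt((rec$gx - proj$rx)^2 + (rec$gy - proj$ry)^2 +
                (rec$gz - proj$rz)^2)
    worst <- max(worst, max(err))
  }
  expect_lt(worst, 1e-9)
})

test_that("the straightness score is minimized near the true axis", {
  run <- small_noisy_run()
  spots <- run$res$spots
  info <- run$res$info
  ax <- refine_tilt_axis(spots, info, scan = c(38, 59, 1.5, 0.25))
  expect_lt(abs(ax$azimuth - 48.5), 1.0)
  sc <- attr(ax, "score_curve")
  s_true <- sc$score[which.min(abs(sc$azimuth - 48.5))]
  expect_lt(s_true, sc$score[which.min(abs(sc$azimuth - 42.5))])
  expect_lt(s_true, sc$score[which.min(abs(sc$azimuth - 54.5))])
})

test_that("the score treats the axis as a line (phi and phi + 180 equal)", {
  expect_equal(tilt_axis(190)$azimuth, 10)
  expect_equal(tilt_axis(48.5)$azimuth, tilt_axis(228.5)$azimuth)
})

test_that("section cutting partitions the cloud and respects offsets", {
  run <- small_noiseless_run()
  res <- run$res
  s3 <- res$spots3d
  B <- unclass(res$basis)
  ## integer-offset cuts of thickness 1 partition all spots
  frac <- solve(B, t(as.matrix(s3[, c("gx", "gy", "gz")])))[3, ]
  offs <- seq(floor(min(frac)), ceiling(max(frac)))
  n_in <- sum(vapply(offs, function(o)
    nrow(cut_section(s3, B, 3, o, thickness = 1.0)), 0L))
  ## boundary points may fall in two adjacent slabs
  expect_gte(n_in, nrow(s3))
  expect_lte(n_in, nrow(s3) * 1.02)
  ## an offset-1 cut excludes the origin region
  cut1 <- cut_section(s3, B, 3, 1, thickness = 0.5)
  if (nrow(cut1) > 0) {
    fr1 <- solve(B, t(as.matrix(cut1[, c("gx", "gy", "gz")])))[3, ]
    expect_true(all(abs(fr1 - 1) <= 0.25 + 1e-12))
  }
  ## plane-normal route agrees with the basis route
  n3 <- B[, 3]
  ## fractional l along c* is g . n / |n|^2 only for orthogonal bases, so
  ## compare with the dual vector instead
  dual <- solve(t(B))[, 3]   # real-space c vector; frac l = g . c
  cut_n <- cut_section(s3, normal = dual, offset = 0, thickness = 0.5,
                       spacing = 1 / sqrt(sum(dual^2)))
  cut_b <- cut_section(s3, B, 3, 0, thickness = 0.5)
  expect_equal(nrow(cut_n), nrow(cut_b))
})

test_that("hk0-type cut of a noiseless run contains the truth l = 0 layer", {
  run <- small_noiseless_run()
  res <- run$res
  sim <- run$sim
  ## use the true lab-frame basis for the cut; the truth l = 0 reflections
  ## recorded by the simulator must be inside, all others outside
  Bt <- sim$truth$basis_lab
  s3 <- res$spots3d
  cut <- cut_section(s3, Bt, 3, 0, thickness = 0.5)
  frac_all <- solve(Bt, t(as.matrix(s3[, c("gx", "gy", "gz")])))
  sel <- abs(frac_all[3, ]) <= 0.25
  expect_equal(nrow(cut), sum(sel))
  expect_gt(nrow(cut), 0)
})
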