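test_that("a single spot merges to a single identical reflection", {
  sp <- data.frame(frame = 1, x = 12, y = -7, gx = 0.1, gy = 0.02,
                   gz = 0.003, raw_peak = 500, saturated = FALSE)
  r <- merge_spots(sp)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$gx, r$gy, r$gz), c(0.1, 0.02, 0.003))
  expect_equal(r$I_max, 500)
  expect_equal(r$I_3d, 500)         # single-member fallback
  expect_true(r$i3d_fallback)
  expect_equal(r$d, 1 / sqrt(0.1^2 + 0.02^2 + 0.003^2))
})

test_that("Eq.-1 integration matches hand evaluation and a brute oracle", {
  ## [1, 2, 1] at equal spacings of 0.01: I_3d = (2 + 1) * 0.01 = 0.03
  m <- data.frame(frame = 1:3, gx = c(0, 0.01, 0.02), gy = 0, gz = 0,
                  I = c(1, 2, 1))
  got <- integrate_reflection_3d(m)
  expect_equal(got$I_3d, 0.03)
  expect_false(got$fallback)
  ## homogeneity: doubling all spacings doubles the integral
  m2 <- m; m2$gx <- m2$gx * 2
  expect_equal(integrate_reflection_3d(m2)$I_3d, 0.06)
  ## randomized oracle equivalence (independent loop implementation)
  oracle <- function(mm) {
    mm <- mm[order(mm$frame), ]
    tot <- 0
    for (i in 2:nrow(mm))
      tot <- tot + mm$I[i] * sqrt(sum((c(mm$gx[i], mm$gy[i], mm$gz[i]) -
                                       c(mm$gx[i - 1], mm$gy[i - 1],
                                         mm$gz[i - 1]))^2))
    tot
  }
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:9, 1)
    mm <- data.frame(frame = sample(100, n), gx = rnorm(n, 0, 0.01),
                     gy = rnorm(n, 0, 0.01), gz = rnorm(n, 0, 0.01),
                     I = runif(n, 0, 1000))
    expect_equal(integrate_reflection_3d(mm)$I_3d, oracle(mm))
  }
})

test_that("merging a noiseless simulation recovers one reflection per hkl", {
  run <- small_noiseless_run()
  sim <- run$sim
  res <- run$res
  ## recorded truth: distinct hkl that produced at least one strong spot
  ## away from the beam stop region, restricted to deduplicated frames
  ct <- round(sim$info$frames$combined_tilt, 5)
  keep_frames <- which(!duplicated(ct))
  tr <- sim$truth$spots
  tr <- tr[tr$frame %in% keep_frames, ]
  beam <- run$res$beam_track
  r2 <- sqrt((tr$x - beam$x[tr$frame])^2 + (tr$y - beam$y[tr$frame])^2)
  margin <- tr$x > 6 & tr$x < 249 & tr$y > 6 & tr$y < 249
  strong <- tr[tr$intensity > 60 & r2 > 18 & margin, ]
  n_truth <- length(unique(paste(strong$h, strong$k, strong$l)))
  ## every such hkl must be represented by at least one merged reflection,
  ## and the total count must not exceed the recorded distinct hkl by much
  expect_gt(nrow(res$reflections), 0.95 * n_truth)
  all_hkl <- length(unique(paste(tr$h, tr$k, tr$l)))
  expect_lt(nrow(res$reflections), 1.05 * all_hkl)
})

test_that("Friedel mates stay separate and appear a few frames apart", {
  run <- small_noiseless_run()
  idx <- run$res$indexed
  acc <- idx[idx$accepted, ]
  key <- paste(acc$h, acc$k, acc$l)
  mate <- match(paste(-acc$h, -acc$k, -acc$l), key)
  have <- which(!is.na(mate) & mate != seq_along(mate))
  expect_gt(length(have), 100)  # mates are present as separate reflections
})

test_that("basis finding recovers exact lattices and rejects 1D input", {
  ## exact lattice points of a known triclinic basis
  B <- cbind(c(0.05, 0.002, 0), c(-0.001, 0.048, 0.003), c(0.01, 0, 0.08))
  hkl <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  g <- hkl %*% t(B)
  df <- data.frame(gx = g[, 1], gy = g[, 2], gz = g[, 3])
  got <- find_reciprocal_basis(df)
  ## found basis must span the same lattice: integer unimodular transform
  Tm <- solve(B) %*% unclass(got)
  expect_lt(max(abs(Tm - round(Tm))), 1e-9)
  expect_equal(abs(det(round(Tm))), 1)
  ## collinear-only difference set fails with a clear error
  df1 <- data.frame(gx = 0.05 * (-10:10), gy = 0, gz = 0)
  expect_error(find_reciprocal_basis(df1), "noncoplanar|clusters")
})

test_that("basis finding is invariant to global rotations of the cloud", {
  ## exact lattice: clusters are coincident points, so the recovered cell
  ## is rotation invariant to numerical precision
  B <- cbind(c(0.05, 0.002, 0), c(-0.001, 0.048, 0.003), c(0.01, 0, 0.08))
  hkl <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  g <- hkl %*% t(B)
  R <- red3d:::rotation_matrix(c(1, 2, 3), 33.3)
  cell0 <- cell_parameters_from_basis(find_reciprocal_basis(
    data.frame(gx = g[, 1], gy = g[, 2], gz = g[, 3])))
  gr <- g %*% t(R)
  cellr <- cell_parameters_from_basis(find_reciprocal_basis(
    data.frame(gx = gr[, 1], gy = gr[, 2], gz = gr[, 3])))
  for (f in c("a", "b", "c", "alpha", "beta", "gamma"))
    expect_equal(cellr[[f]], cell0[[f]], tolerance = 1e-9)
  ## noisy clouds: cluster membership and the reduced-cell setting are not
  ## exactly orientation independent, so the invariant tested is lattice
  ## equivalence (integer unimodular relation after rotating back) plus
  ## agreement of the rotation-invariant cell volume
  run <- small_noisy_run()
  gn <- as.matrix(run$res$reflections[, c("gx", "gy", "gz")])
  B0 <- unclass(find_reciprocal_basis(
    data.frame(gx = gn[, 1], gy = gn[, 2], gz = gn[, 3])))
  gnr <- gn %*% t(R)
  Br <- unclass(find_reciprocal_basis(
    data.frame(gx = gnr[, 1], gy = gnr[, 2], gz = gnr[, 3])))
  Bb <- t(R) %*% Br                      # rotate back
  Tm <- solve(B0) %*% Bb
  expect_lt(max(abs(Tm - round(Tm))), 0.05)
  expect_equal(abs(det(round(Tm))), 1)
  expect_equal(abs(det(Bb)), abs(det(B0)), tolerance = 5e-3)
})

test_that("cell parameters derive correctly from a reciprocal basis", {
  ## orthonormal x 0.1 -> cubic 10 A cell
  cell <- cell_parameters_from_basis(diag(3) * 0.1)
  expect_equal(c(cell$a, cell$b, cell$c), c(10, 10, 10))
  expect_equal(c(cell$alpha, cell$beta, cell$gamma), c(90, 90, 90))
  ## identity transform is a no-op; a valid cell-doubling transform works
  B <- red3d:::reciprocal_matrix(unit_cell(20.02, 20.25, 13.35, 90, 90.74,
                                           90))
  c1 <- cell_parameters_from_basis(B, diag(3))
  expect_equal(c1$beta, 90.74, tolerance = 1e-9)
  c2 <- cell_parameters_from_basis(B, diag(c(1, 1, 2)))
  expect_equal(c2$c, 13.35 / 2, tolerance = 1e-9)
  expect_error(cell_parameters_from_basis(matrix(0, 3, 3)), "singular")
})

test_that("adaptive indexing matches its defining examples", {
  cell <- unit_cell(20.02, 20.25, 13.35, 90, 90.74, 90)
  B <- red3d:::reciprocal_matrix(cell)
  ## a reflection at fractional (0.97, 0.95, 0.01) is accepted as 1 1 0
  g <- as.vector(B %*% c(0.97, 0.95, 0.01))
  refl <- data.frame(gx = g[1], gy = g[2], gz = g[3])
  idx <- index_reflections(refl, B, index_params(0.1))
  expect_true(idx$accepted)
  expect_equal(c(idx$h, idx$k, idx$l), c(1, 1, 0))
  expect_equal(c(idx$h_frac, idx$k_frac, idx$l_frac),
               c(0.97, 0.95, 0.01), tolerance = 1e-10)
  ## deviation 0.15 on one axis with threshold 0.1 is rejected
  g2 <- as.vector(B %*% c(1.15, 1.0, 0.0))
  idx2 <- index_reflections(data.frame(gx = g2[1], gy = g2[2], gz = g2[3]),
                            B, index_params(0.1))
  expect_false(idx2$accepted)
  expect_equal(idx2$deviation, 0.15, tolerance = 1e-10)
})

test_that("indexing of exact lattice positions has ~zero deviation", {
  cell <- unit_cell(20.02, 20.25, 13.35, 90, 90.74, 90)
  B <- red3d:::reciprocal_matrix(cell)
  O <- red3d:::rotation_matrix(c(3, -1, 2), 77)
  hkl <- as.matrix(expand.grid(-6:6, -6:6, -6:6))
  g <- hkl %*% t(O %*% B)
  idx <- index_reflections(data.frame(gx = g[, 1], gy = g[, 2],
                                      gz = g[, 3]), O %*% B)
  expect_true(all(idx$accepted))
  expect_lt(max(idx$deviation), 1e-6)
  ## recovered integer indices match the construction
  expect_equal(cbind(idx$h, idx$k, idx$l), unname(hkl))
})

test_that("indexing survives a deliberately bent reconstruction", {
  ## reconstruct the noiseless small dataset with the axis off by 2 degrees
  run <- small_noiseless_run()
  sim <- run$sim
  spots <- run$res$spots
  info <- run$res$info
  s3 <- map_to_3d(spots, info, tilt_axis(48.5 + 2))
  refl <- merge_spots(s3, intensity_col = "raw_peak")
  basis0 <- find_reciprocal_basis(refl)
  idx <- index_reflections(refl, refine_basis(index_reflections(refl,
                                                                basis0)))
  ## most reflections still pass the +/-0.1 threshold despite the bending
  expect_gt(mean(idx$accepted), 0.85)
  ## ground-truth check: match each accepted reflection's strongest spot to
  ## the simulator truth, estimate the integer transform between assigned
  ## and true indices, and require > 99% agreement
  acc <- idx[idx$accepted, ]
  beam <- run$res$beam_track
  tr <- sim$truth$spots
  ht <- matrix(NA_real_, nrow(acc), 3)
  for (i in seq_len(nrow(acc))) {
    tf <- tr[tr$frame == acc$frame_of_max[i], ]
    d <- sqrt((tf$x - beam$x[acc$frame_of_max[i]] - acc$x[i])^2 +
              (tf$y - beam$y[acc$frame_of_max[i]] - acc$y[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] < 1.5) ht[i, ] <- c(tf$h[j], tf$k[j], tf$l[j])
  }
  ok <- !is.na(ht[, 1])
  expect_gt(mean(ok), 0.95)
  Ha <- cbind(acc$h, acc$k, acc$l)[ok, ]
  Ht <- ht[ok, ]
  P <- round(t(solve(crossprod(Ht), crossprod(Ht, Ha))))
  expect_equal(abs(det(P)), 1)
  correct <- rowSums(abs(Ha - Ht %*% t(P))) == 0
  expect_gt(mean(correct), 0.99)
  ## and the derived cell stays within 1% of the truth
  true_cell <- unit_cell(20.02, 20.25, 13.35, 90, 90.74, 90)
  expect_lt(cell_match_error(basis0, true_cell), 1)
})

test_that("absence statistics behave on constructed classes", {
  ## all-ones intensities: every non-empty class mean is 1
  hkl <- expand.grid(h = -3:3, k = -3:3, l = -3:3)
  idx <- data.frame(hkl, I_max = 1, accepted = TRUE)
  tab <- absence_statistics(idx)
  expect_true(all(tab$mean_I[tab$n > 0] == 1))
  ## an empty class reports n = 0 and NA means
  idx2 <- data.frame(h = c(2, 4), k = 0, l = 0, I_max = c(5, 7),
                     accepted = TRUE)
  tab2 <- absence_statistics(idx2)
  row <- tab2[tab2$class == "h00: h odd (2_1 axis)", ]
  expect_equal(row$n, 0)
  expect_true(is.na(row$mean_I))
  ## a synthetic n-glide extinction shows up as a weak class
  set.seed(5)
  hkl3 <- expand.grid(h = -4:4, k = -4:4, l = -4:4)
  I <- runif(nrow(hkl3), 500, 1500)
  extinct <- hkl3$k == 0 & (hkl3$h + hkl3$l) %% 2 != 0
  I[extinct] <- runif(sum(extinct), 0, 2)   # background-level leakage
  idx3 <- data.frame(hkl3, I_max = I, accepted = TRUE)
  tab3 <- absence_statistics(idx3)
  glide <- tab3[tab3$class == "h0l: h+l odd (n glide)", ]
  ref <- tab3[tab3$class == "h0l: h odd (a glide)", ]
  expect_lt(glide$mean_I, 5)
  expect_gt(ref$mean_I, 100)
})
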