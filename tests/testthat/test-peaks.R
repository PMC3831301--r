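## analytic frame with Gaussian spots at known positions
spot_frame <- function(n = 128, spots, sigma = 1.2, background = 0) {
  img <- matrix(background, n, n)
  for (i in seq_len(nrow(spots)))
    img <- red3d:::add_gaussian(img, spots$x[i], spots$y[i], sigma,
                                spots$I[i], as.integer(ceiling(6 * sigma)))
  img
}

test_that("flat frames yield no spots and thresholds are monotone", {
  expect_equal(nrow(hunt_peaks(matrix(7, 64, 64))), 0)
  sp <- data.frame(x = c(30, 70, 100), y = c(40, 60, 90), I = c(50, 200, 800))
  img <- spot_frame(128, sp)
  p_lo <- peak_hunt_params(threshold = 10)
  p_hi <- peak_hunt_params(threshold = 60)
  n_lo <- nrow(hunt_peaks(img, p_lo))
  n_hi <- nrow(hunt_peaks(img, p_hi))
  expect_equal(n_lo, 3)
  expect_lte(n_hi, n_lo)
  expect_equal(n_hi, 2)
})

test_that("two close spots merge into one detection at the brighter maximum", {
  sp <- data.frame(x = c(60, 63), y = c(60, 60), I = c(300, 400))
  img <- spot_frame(128, sp, sigma = 1.5)
  got <- hunt_peaks(img, peak_hunt_params(threshold = 20))
  expect_equal(nrow(got), 1)
  expect_equal(got$x, 63, tolerance = 1)
})

test_that("detection is translation-equivariant for integer shifts", {
  sp <- data.frame(x = c(30, 70, 95), y = c(40, 65, 20), I = c(100, 400, 900))
  img <- spot_frame(128, sp)
  img2 <- matrix(0, 128, 128)
  img2[11:128, 6:128] <- img[1:118, 1:123]  # shift by (+5, +10)
  a <- hunt_peaks(img, peak_hunt_params(threshold = 20))
  b <- hunt_peaks(img2, peak_hunt_params(threshold = 20))
  b <- b[b$x >= 6 & b$y >= 11, ]
  expect_equal(nrow(a), nrow(b))
  expect_setequal(paste(a$x + 5, a$y + 10), paste(b$x, b$y))
})

test_that("noiseless simulated frames are detected where truth says", {
  run <- sparse_noiseless_run()
  sim <- run$sim
  checked <- 0
  for (fr in c(4, 9, 15)) {
    img <- read_mrc(file.path(run$dir, sim$info$frames$filename[fr]))
    got <- hunt_peaks(img, peak_hunt_params(threshold = 15),
                      beam_centre = c(127.5, 127.5),
                      saturation_level = 4095)
    tr <- sim$truth$spots[sim$truth$spots$frame == fr, ]
    ## strong, isolated truth spots away from the beam skirt and edges:
    ## within ~35 px of the direct beam its sigma-12 blurred footprint
    ## inflates the background estimate and weak spots are (correctly, per
    ## the algorithm) suppressed
    keep <- tr$intensity > 60 &
      sqrt((tr$x - 127.5)^2 + (tr$y - 127.5)^2) > 40 &
      tr$x > 6 & tr$x < 249 & tr$y > 6 & tr$y < 249
    for (i in which(keep)) {
      others <- sqrt((tr$x - tr$x[i])^2 + (tr$y - tr$y[i])^2)
      if (sum(others < 6) > 1) next
      dmin <- min(sqrt((got$x - tr$x[i])^2 + (got$y - tr$y[i])^2))
      expect_lt(dmin, 1.01)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 30)
})

test_that("integrated intensities follow their defining contracts", {
  ## delta spot of height H on zero background integrates to H
  img <- matrix(0, 64, 64)
  img[33, 41] <- 250
  sp <- data.frame(x = 40, y = 32, raw_peak = 250, smoothed_peak = NA,
                   npix = 1L, saturated = FALSE)
  got <- extract_intensities(img, sp, mode = "integrated")
  expect_equal(got$integrated, 250)
  expect_false(got$partial)
  ## constant background cancels exactly
  img2 <- matrix(17.3, 64, 64)
  got2 <- extract_intensities(img2, sp, mode = "integrated")
  expect_equal(got2$integrated, 0, tolerance = 1e-10)
  ## window clipped by the edge is flagged partial
  spe <- sp; spe$x <- 2; spe$y <- 2
  expect_true(extract_intensities(img, spe, mode = "integrated")$partial)
})

test_that("integration matches the continuous Gaussian integral within 2%", {
  sigma <- 1.2
  sp <- data.frame(x = 60, y = 60, I = 1000)
  img <- spot_frame(128, sp, sigma = sigma)
  peak <- max(img)
  spots <- data.frame(x = 60, y = 60, raw_peak = peak, smoothed_peak = NA,
                      npix = 1L, saturated = FALSE)
  got <- extract_intensities(img, spots, mode = "integrated",
                             window_radius = 6, annulus_width = 3)
  expect_equal(got$integrated, 2 * pi * sigma^2 * peak, tolerance = 0.02)
})

test_that("integrated intensity is linear against simulator truth", {
  run <- sparse_noiseless_run()
  sim <- run$sim
  tr <- sim$truth$spots
  ## detect + integrate on noiseless, driftless frames (beam at centre)
  spot_list <- list()
  for (fr in seq_len(nrow(sim$info$frames))) {
    img <- read_mrc(file.path(run$dir, sim$info$frames$filename[fr]))
    sp <- hunt_peaks(img, peak_hunt_params(threshold = 15),
                     beam_centre = c(127.5, 127.5),
                     saturation_level = 4095)
    if (nrow(sp) == 0) next
    sp <- extract_intensities(img, sp, mode = "integrated")
    sp$frame <- fr
    spot_list[[length(spot_list) + 1]] <- sp
  }
  spots <- do.call(rbind, spot_list)
  beam <- data.frame(frame = seq_len(nrow(sim$info$frames)),
                     x = 0, y = 0)          # absolute coordinates kept
  frames <- sort(unique(spots$frame))
  sigma <- 1.2
  ## oracle: the renderer scales a Gaussian so its maximum pixel equals the
  ## truth intensity; the expected 2D integral over the window follows in
  ## closed form from the continuous truth position
  predicted_integral <- function(I, x0, y0, radius = 5) {
    xs <- (round(x0) - 8):(round(x0) + 8)
    ys <- (round(y0) - 8):(round(y0) + 8)
    blob <- outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
                  exp(-(xs - x0)^2 / (2 * sigma^2)))
    disc <- outer((ys - round(y0))^2, (xs - round(x0))^2, "+") <= radius^2
    I / max(blob) * sum(blob[disc])
  }
  I_est <- I_pred <- numeric(0)
  for (fr in frames) {
    s <- spots[spots$frame == fr & !spots$partial & !spots$saturated, ]
    t <- tr[tr$frame == fr, ]
    for (i in seq_len(nrow(s))) {
      d <- sqrt((t$x - beam$x[fr] - s$x[i])^2 +
                (t$y - beam$y[fr] - s$y[i])^2)
      j <- which.min(d)
      if (length(j) && d[j] < 1.5 && sum(d < 8) == 1) {
        I_est <- c(I_est, s$integrated[i])
        I_pred <- c(I_pred, predicted_integral(t$intensity[j], t$x[j],
                                               t$y[j]))
      }
    }
  }
  expect_gt(length(I_est), 50)
  fit <- stats::lm(I_est ~ I_pred)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.01)
})
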