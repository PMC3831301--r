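## Shared fixtures, built in code. Small simulations are cached per session
## so several test files can reuse them without re-rendering.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, .fixture_env)) assign(name, fun(), .fixture_env)
  get(name, .fixture_env)
}

## a small but complete experiment: 256x256 detector, +/-40 deg, moderate
## resolution; ~200 frames, renders in a few seconds
small_sim_config <- function(seed = 7, poisson = TRUE, drift = 0.2, ...) {
  sim_config(schedule = tilt_schedule(-40, 40, 2, 1.0, 0.5),
             detector_shape = c(256L, 256L),
             pixels_per_inv_angstrom = 140,
             d_min = 1.6, poisson_noise = poisson,
             drift_step_sigma = drift, seed = seed, ...)
}

small_noiseless_config <- function(seed = 7, ...)
  small_sim_config(seed = seed, poisson = FALSE, drift = 0, ...)

## rendered small noisy dataset + pipeline run (used by several files)
small_noisy_run <- function() fixture("small_noisy_run", function() {
  dir <- file.path(tempdir(), "red3d_small_noisy")
  sim <- render_dataset(small_sim_config(), dir)
  res <- run_pipeline(pipeline_config(dir, tilt_axis = "info"))
  list(dir = dir, sim = sim, res = res)
})

small_noiseless_run <- function() fixture("small_noiseless_run", function() {
  dir <- file.path(tempdir(), "red3d_small_noiseless")
  sim <- render_dataset(small_noiseless_config(), dir)
  res <- run_pipeline(pipeline_config(dir, tilt_axis = "info"))
  list(dir = dir, sim = sim, res = res)
})

## sparse geometry: lattice nodes ~14 px apart on the detector, noiseless
## and driftless, so individual spots are well separated and the beam sits
## exactly at the detector centre (127.5, 127.5)
sparse_noiseless_run <- function() fixture("sparse_noiseless_run", function() {
  dir <- file.path(tempdir(), "red3d_sparse_noiseless")
  cfg <- sim_config(schedule = tilt_schedule(-6, 6, 2, 0.5, 0.5),
                    detector_shape = c(256L, 256L),
                    pixels_per_inv_angstrom = 280, d_min = 2.4,
                    poisson_noise = FALSE, drift_step_sigma = 0, seed = 17)
  sim <- render_dataset(cfg, dir)
  list(dir = dir, cfg = cfg, sim = sim)
})

random_experiment_info <- function(n_frames = 5) {
  frames <- data.frame(
    filename = sprintf("f_%03d.mrc", seq_len(n_frames)),
    goniometer_tilt = seq(-10, 10, length.out = n_frames),
    beam_tilt = round(stats::runif(n_frames, -1, 1), 4))
  frames$combined_tilt <- frames$goniometer_tilt + frames$beam_tilt
  ## keep combined tilts strictly increasing
  frames <- frames[order(frames$combined_tilt), ]
  frames <- frames[!duplicated(round(frames$combined_tilt, 5)), ]
  frames$filename <- sprintf("f_%03d.mrc", seq_len(nrow(frames)))
  experiment_info(
    wavelength = round(stats::runif(1, 0.019, 0.034), 4),
    pixels_per_inv_angstrom = round(stats::runif(1, 100, 400), 3),
    tilt_axis_azimuth = round(stats::runif(1, 0, 180), 4),
    frames = frames,
    detector_shape = sample(c(256L, 512L, 1024L), 2, replace = TRUE),
    bit_depth = sample(c(12L, 14L, 16L), 1))
}

## best signed-permutation match of a recovered basis to a reference cell:
## returns the smallest max relative error (%) over the six cell parameters
cell_match_error <- function(basis, true_cell) {
  truth <- c(true_cell$a, true_cell$b, true_cell$c,
             true_cell$alpha, true_cell$beta, true_cell$gamma)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- Inf
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1))
    for (s3 in c(1, -1)) {
      Tm <- matrix(0, 3, 3)
      Tm[1, p[1]] <- s1; Tm[2, p[2]] <- s2; Tm[3, p[3]] <- s3
      cl <- tryCatch(cell_parameters_from_basis(basis, Tm),
                     error = function(e) NULL)
      if (is.null(cl)) next
      v <- c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
      best <- min(best, max(abs(v - truth) / truth * 100))
    }
  best
}
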