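test_that("acquisition configuration derives frame count and interval", {
  cfg <- acq_config(frame_rate_hz = 512, duration_s = 10)
  expect_equal(cfg$n_frames, 5120L)
  expect_equal(cfg$dt_s, 1 / 512)
  cfg2 <- acq_config(frame_rate_hz = 100, duration_s = 0.5)
  expect_equal(cfg2$n_frames, 50L)
})

test_that("simulation is reproducible and seed-sensitive", {
  cfg <- acq_config(duration_s = 0.1, seed = 7)
  a <- simulate_trajectories(3, motion_free(0.1), cfg)
  b <- simulate_trajectories(3, motion_free(0.1), cfg)
  expect_equal(a$x_um, b$x_um)
  expect_equal(a$y_um, b$y_um)
  cfg2 <- acq_config(duration_s = 0.1, seed = 8)
  c <- simulate_trajectories(3, motion_free(0.1), cfg2)
  expect_false(identical(a$x_um, c$x_um))
})

test_that("per-particle streams are independent of particle count", {
  cfg <- acq_config(duration_s = 0.1, seed = 7)
  small <- simulate_trajectories(3, motion_free(0.1), cfg)
  large <- simulate_trajectories(6, motion_free(0.1), cfg)
  for (id in c("p001", "p002", "p003")) {
    expect_equal(small$x_um[small$particle_id == id],
                 large$x_um[large$particle_id == id])
  }
})

test_that("free-motion increments have the exact per-axis variance", {
  cfg <- acq_config(duration_s = 2, seed = 11)
  tr <- simulate_trajectories(20, motion_free(0.1), cfg)
  dx <- unlist(lapply(split(tr$x_um, tr$particle_id), diff))
  n <- length(dx)
  v <- var(dx)
  target <- 2 * 0.1 * cfg$dt_s
  # chi-square spread of a sample variance: sd ~ target * sqrt(2/n)
  expect_lt(abs(v - target), 4 * target * sqrt(2 / n))
  expect_lt(abs(mean(dx)), 4 * sqrt(target / n))
})

test_that("confined motion reproduces the analytic OU plateau", {
  tau_r <- 0.02
  D <- 0.1
  cfg <- acq_config(frame_rate_hz = 1000, duration_s = 2, seed = 5)
  tr <- simulate_trajectories(60, motion_confined(D, tau_r), cfg)
  msd <- compute_msd(tr, lags = c(1, 5, 20, 100, 400))
  em <- ensemble_msd(msd)
  expected <- ou_msd(em$lag_s, D, tau_r)
  # stationary start: analytic MSD holds at every lag, within 4 SE
  expect_true(all(abs(em$msd_um2 - expected) < 4 * em$se))
})

test_that("drifting preset equals free preset plus recorded rigid drift", {
  free <- cached_fixture("free_jurkat_like", render = FALSE)$truth
  drif <- cached_fixture("drifting", render = FALSE)$truth
  drift <- attr(drif, "drift")
  joined <- dplyr::left_join(drif, drift, by = "frame")
  expect_equal(joined$x_um - joined$dx_um, free$x_um, tolerance = 1e-12)
  expect_equal(joined$y_um - joined$dy_um, free$y_um, tolerance = 1e-12)
  # cumulative drift is v * dt * (frame - 1)
  expect_equal(drift$dx_um, 0.2 * (drift$frame - 1) / 512)
  expect_equal(drift$dy_um, 0.1 * (drift$frame - 1) / 512)
})

test_that("minimum separation of initial positions is enforced", {
  cfg <- acq_config(duration_s = 0.05, seed = 3)
  tr <- simulate_trajectories(10, motion_free(0.1), cfg,
                              min_separation_um = 2)
  p0 <- dplyr::filter(tr, frame == 1)
  d <- as.matrix(dist(cbind(p0$x_um, p0$y_um)))
  expect_true(all(d[upper.tri(d)] >= 2))
})

test_that("invalid simulation inputs are rejected", {
  cfg <- acq_config(duration_s = 0.05, seed = 1)
  expect_error(simulate_trajectories(0, motion_free(0.1), cfg))
  expect_error(simulate_trajectories(2, motion_free(0.1), cfg,
                                     diameter_range_um = c(-1, 1)))
  expect_error(motion_confined(0.1, tau_r = -1))
  expect_error(acq_config(frame_rate_hz = -5))
})

test_that("truth table carries the documented columns and attributes", {
  cfg <- acq_config(duration_s = 0.05, seed = 2)
  tr <- simulate_trajectories(2, motion_confined(0.1, 0.05), cfg)
  expect_true(all(c("nucleus_id", "particle_id", "frame", "t_s",
                    "x_um", "y_um", "diameter_um", "intensity") %in%
                    names(tr)))
  expect_s3_class(tr, "ptmr_truth")
  expect_equal(attr(tr, "model")$tau_r, 0.05)
  expect_equal(nrow(tr), 2 * cfg$n_frames)
})
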