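test_that("MSD reproduces the hand-enumerated three-point example", {
  tr <- tibble::tibble(particle_id = "p1", frame = 1:3, t_s = 0:2,
                       x_um = c(0, 1, 1), y_um = c(0, 0, 1))
  msd <- compute_msd(tr, max_lag_fraction = 1, min_length = 3)
  expect_equal(msd$lag_s, c(1, 2))
  expect_equal(msd$msd_um2, c(1, 2))          # (1+1)/2 then 2/1
  expect_equal(msd$n_origins, c(2L, 1L))
})

test_that("MSD of a constant trajectory is zero", {
  tr <- tibble::tibble(particle_id = "p1", frame = 1:20, t_s = 0:19,
                       x_um = 3, y_um = -2)
  msd <- compute_msd(tr, min_length = 8)
  expect_true(all(msd$msd_um2 == 0))
})

test_that("MSD is invariant under time reversal", {
  set.seed(6)
  tr <- tibble::tibble(particle_id = "p1", frame = 1:50, t_s = 0:49,
                       x_um = cumsum(rnorm(50)), y_um = cumsum(rnorm(50)))
  rev <- dplyr::mutate(tr, x_um = rev(x_um), y_um = rev(y_um))
  expect_equal(compute_msd(tr)$msd_um2, compute_msd(rev)$msd_um2)
})

test_that("2D MSD is the sum of the per-axis MSDs", {
  set.seed(7)
  tr <- tibble::tibble(particle_id = "p1", frame = 1:40, t_s = 0:39,
                       x_um = cumsum(rnorm(40)), y_um = cumsum(rnorm(40)))
  trx <- dplyr::mutate(tr, y_um = 0)
  try_ <- dplyr::mutate(tr, x_um = 0)
  expect_equal(compute_msd(tr)$msd_um2,
               compute_msd(trx)$msd_um2 + compute_msd(try_)$msd_um2)
})

test_that("gaps and short trajectories are rejected", {
  gap <- tibble::tibble(particle_id = "p1", frame = c(1:5, 7:12),
                        t_s = c(1:5, 7:12), x_um = 0, y_um = 0)
  expect_error(compute_msd(gap, min_length = 5), "gaps")
  short <- tibble::tibble(particle_id = "p1", frame = 1:4, t_s = 1:4,
                          x_um = 0, y_um = 0)
  expect_error(compute_msd(short), "short")
})

test_that("non-overlapping origins use independent windows", {
  tr <- tibble::tibble(particle_id = "p1", frame = 1:9, t_s = 0:8,
                       x_um = c(0, 1, 1, 2, 2, 3, 3, 4, 4), y_um = 0)
  msd <- compute_msd(tr, lags = 2, overlapping = FALSE, min_length = 5)
  expect_equal(msd$n_origins, 4L)   # origins 1, 3, 5, 7
  expect_equal(msd$msd_um2, 1)
})

test_that("diffusion fit inverts the exact free-diffusion law", {
  lag <- (1:20) / 100
  msd <- tibble::tibble(particle_id = "p1", lag_s = lag,
                        msd_um2 = 0.4 * lag,
                        n_origins = rev(seq_along(lag)))
  fit <- fit_diffusion(msd, max_lag_s = 0.1)
  expect_equal(fit$D_eff_um2_s, 0.1, tolerance = 1e-12)
  tidied <- tidy(fit)
  expect_s3_class(tidied, "tbl_df")
  expect_false(inherits(tidied, "diffusion_fit"))
  expect_true(all(c("particle_id", "D_eff_um2_s") %in% names(tidied)))
  gl <- glance(fit)
  expect_equal(gl$n_particles, 1L)
  expect_equal(gl$D_mean_um2_s, 0.1, tolerance = 1e-12)
})

test_that("negative MSD slopes clamp to zero diffusivity with a flag", {
  lag <- (1:10) / 100
  # pathological input whose weighted through-origin slope is negative
  msd <- tibble::tibble(particle_id = "p1", lag_s = lag,
                        msd_um2 = 0.001 - 0.4 * lag,
                        n_origins = rev(seq_along(lag)))
  fit <- fit_diffusion(msd, max_lag_s = 0.1)
  expect_equal(fit$D_eff_um2_s, 0)
  expect_equal(fit$flag, "negative_slope")
  eta <- estimate_viscosity(fit, R_um = 0.5)
  expect_true(is.infinite(eta$eta_app_Pa_s))
  expect_equal(eta$flag, "zero_diffusivity")
})

test_that("anomalous exponent is exact on power-law inputs", {
  lag <- (1:30) / 100
  for (a in c(0.5, 1, 1.5)) {
    msd <- tibble::tibble(particle_id = "p1", lag_s = lag,
                          msd_um2 = 0.2 * lag^a)
    # suppress lm's "essentially perfect fit" note on exact inputs
    fit <- suppressWarnings(fit_anomalous_exponent(msd))
    expect_equal(fit$alpha, a, tolerance = 1e-10)
  }
})

test_that("viscosity estimator reproduces the worked numeric example", {
  eta <- estimate_viscosity(0.4366, R_um = 0.5, temperature_K = 298)
  expect_equal(eta$eta_app_Pa_s, 1.000e-3, tolerance = 1e-3)
  # eta is inversely proportional to R at fixed D
  eta2 <- estimate_viscosity(0.4366, R_um = 1.0, temperature_K = 298)
  expect_equal(eta2$eta_app_Pa_s, eta$eta_app_Pa_s / 2)
})

test_that("Stokes-Einstein round trip is exact to floating point", {
  set.seed(8)
  for (k in 1:10) {
    eta_true <- 10^runif(1, -4, 1)
    R <- runif(1, 0.1, 2)
    T_K <- runif(1, 250, 350)
    D <- kB * T_K / (6 * pi * eta_true * (R * 1e-6)) * 1e12
    est <- estimate_viscosity(D, R_um = R, temperature_K = T_K)
    expect_equal(est$eta_app_Pa_s, eta_true, tolerance = 1e-12)
  }
})

test_that("viscosity estimator rejects unphysical inputs", {
  expect_error(estimate_viscosity(-0.1, R_um = 0.5), "Diffusivities")
  expect_error(estimate_viscosity(0.1, R_um = -0.5), "Radii")
  expect_error(estimate_viscosity(0.1, R_um = 0.5, temperature_K = 0),
               "temperature")
})

test_that("ensemble MSD averages across particles with standard errors", {
  tr <- tibble::tibble(
    particle_id = rep(c("a", "b"), each = 10),
    frame = rep(1:10, 2), t_s = rep(0:9, 2),
    x_um = c(seq(0, 0.9, by = 0.1), seq(0, 1.8, by = 0.2)), y_um = 0)
  em <- ensemble_msd(compute_msd(tr, min_length = 10, lags = 1))
  expect_equal(em$n_particles, 2L)
  expect_equal(em$msd_um2, mean(c(0.01, 0.04)))
  expect_equal(em$se, sd(c(0.01, 0.04)) / sqrt(2))
})
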