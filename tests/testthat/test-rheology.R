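# Exact power-law MSD table: msd = A * lag^alpha on a log-spaced grid.
power_msd <- function(alpha, A = 0.4, n = 40) {
  lag <- 10^seq(-3, 0, length.out = n)
  tibble::tibble(particle_id = "p1", lag_s = lag, msd_um2 = A * lag^alpha)
}

test_that("the local log-slope estimator is exact for power laws", {
  lag <- 10^seq(-2, 0, length.out = 25)
  for (a in c(-0.3, 0, 0.5, 1, 1.4)) {
    sl <- ptmr:::local_log_slope(log(lag), log(2 * lag^a))
    expect_equal(sl, rep(a, 25), tolerance = 1e-9)
  }
})

test_that("phase follows delta = (pi/2) alpha on exact power laws", {
  for (a in c(0, 0.5, 1)) {
    spec <- mason_modulus(power_msd(a), R_um = 0.5)
    interior <- !spec$endpoint & !spec$masked
    if (a == 1) interior <- interior & spec$alpha_local < 1.4999
    expect_true(any(interior))
    expect_equal(spec$delta_rad[interior],
                 rep(a * pi / 2, sum(interior)), tolerance = 1e-6)
  }
})

test_that("a free-diffusion MSD yields the Stokes-Einstein viscosity", {
  D <- 0.1; R <- 0.5; T_K <- 298
  spec <- mason_modulus(power_msd(1, A = 4 * D), R_um = R,
                        temperature_K = T_K)
  eta_expected <- kB * T_K / (6 * pi * (R * 1e-6) * (D * 1e-12))
  interior <- !spec$endpoint & !spec$masked
  expect_true(all(abs(spec$eta_Pa_s[interior] / eta_expected - 1) < 0.01))
  # purely viscous: storage modulus negligible against loss modulus
  expect_true(all(spec$Gp_Pa[interior] < 0.05 * spec$Gpp_Pa[interior]))
})

test_that("a plateau MSD yields the elastic plateau modulus", {
  A <- 0.02; R <- 0.5; T_K <- 298
  spec <- mason_modulus(power_msd(0, A = A), R_um = R, temperature_K = T_K)
  Gp_expected <- 2 * kB * T_K / (3 * pi * (R * 1e-6) * (A * 1e-12))
  interior <- !spec$endpoint & !spec$masked
  expect_equal(spec$Gd_Pa[interior], rep(Gp_expected, sum(interior)),
               tolerance = 1e-6)
  expect_equal(spec$delta_rad[interior], rep(0, sum(interior)),
               tolerance = 1e-6)
  expect_equal(spec$Gp_Pa[interior], spec$Gd_Pa[interior])
})

test_that("frequencies are exactly the reciprocal lags", {
  spec <- mason_modulus(power_msd(0.5), R_um = 0.5)
  expect_equal(sort(spec$omega_rad_s), sort(1 / spec$lag_s))
})

test_that("the Laplace-domain evaluation agrees with the analytic form", {
  spec <- mason_modulus(power_msd(0.5, n = 120), R_um = 0.5)
  gl <- gser_laplace(power_msd(0.5, n = 120), R_um = 0.5,
                     s_values = c(20, 50, 100))
  gd <- approx(spec$omega_rad_s, spec$Gd_Pa, xout = gl$s)$y
  expect_true(all(abs(gl$G_Pa / gd - 1) < 0.05))
})

test_that("slopes outside the Gamma pole window are masked", {
  # MSD rising as tau^1.8 exceeds the alpha < 1.5 validity range
  spec <- mason_modulus(power_msd(1.8), R_um = 0.5)
  expect_true(all(is.na(spec$Gd_Pa[spec$masked])))
  expect_true(any(spec$masked))
})

test_that("Voigt summary recovers spring and dashpot of an exact OU MSD", {
  D <- 0.1; tau_r <- 0.05; R <- 0.5; T_K <- 298
  lag <- 10^seq(log10(tau_r / 50), log10(20 * tau_r), length.out = 60)
  msd <- tibble::tibble(particle_id = "p1", lag_s = lag,
                        msd_um2 = ou_msd(lag, D, tau_r))
  spec <- mason_modulus(msd, R_um = R, temperature_K = T_K)
  v <- fit_voigt(spec)
  Gp_expected <- 2 * kB * T_K /
    (3 * pi * (R * 1e-6) * (4 * D * tau_r * 1e-12))
  eta_expected <- kB * T_K / (6 * pi * (R * 1e-6) * (D * 1e-12))
  expect_equal(v$Gp_Pa, Gp_expected, tolerance = 0.05)
  expect_equal(v$eta_Pa_s, eta_expected, tolerance = 0.05)
  expect_false(v$non_plateau)
  # the recovered relaxation time is the dashpot/spring ratio
  expect_equal(v$eta_Pa_s / v$Gp_Pa, tau_r, tolerance = 0.1)
  gl <- glance(v)
  expect_equal(gl$n_particles, 1L)
})

test_that("spectra narrower than a decade are rejected", {
  lag <- seq(0.01, 0.05, length.out = 10)
  msd <- tibble::tibble(particle_id = "p1", lag_s = lag,
                        msd_um2 = 0.4 * lag)
  spec <- mason_modulus(msd, R_um = 0.5)
  expect_error(fit_voigt(spec), "decade")
})
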