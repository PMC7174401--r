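# Hand-built multi-particle trajectory table around fixed offsets.
rigid_world <- function(n_frames = 30, n_particles = 5, seed = 1) {
  set.seed(seed)
  base <- tibble::tibble(
    particle_id = sprintf("p%02d", seq_len(n_particles)),
    x0 = runif(n_particles, 2, 8), y0 = runif(n_particles, 2, 8),
    intensity = runif(n_particles, 80, 120))
  tidyr::crossing(base, frame = seq_len(n_frames)) |>
    dplyr::mutate(x_um = x0, y_um = y0, diameter_um = 1,
                  t_s = (frame - 1) / 100) |>
    dplyr::select(particle_id, frame, t_s, x_um, y_um, diameter_um,
                  intensity)
}

test_that("a constant per-frame translation is removed exactly", {
  tr <- rigid_world()
  shifted <- dplyr::mutate(tr, x_um = x_um + 0.25 * (frame - 1),
                           y_um = y_um + 0.25 * (frame - 1))
  corr_static <- drift_correct(tr)
  corr_shift <- drift_correct(shifted)
  expect_equal(corr_shift$x_corr_um, corr_static$x_corr_um,
               tolerance = 1e-10)
  expect_equal(corr_shift$y_corr_um, corr_static$y_corr_um,
               tolerance = 1e-10)
  # static particles end up exactly at their COM offsets, frozen in time
  spread <- tapply(corr_shift$x_corr_um, corr_shift$particle_id, sd)
  expect_true(all(spread < 1e-10))
})

test_that("a growing rigid rotation is removed by the rigid mode", {
  tr <- rigid_world()
  rot <- dplyr::mutate(tr, th = 0.01 * (frame - 1),
                       xr = cos(th) * x_um - sin(th) * y_um,
                       yr = sin(th) * x_um + cos(th) * y_um,
                       x_um = xr, y_um = yr)
  rot <- dplyr::select(rot, -th, -xr, -yr)
  corr <- drift_correct(rot, method = "rigid_com")
  spread <- tapply(corr$x_corr_um, corr$particle_id, sd)
  expect_true(all(spread < 1e-8))
  rec <- attr(corr, "drift_record")
  # recovered per-frame rotation matches the construction
  expect_equal(rec$theta_rad[2] - rec$theta_rad[1], 0.01,
               tolerance = 1e-8)
  # pure COM subtraction cannot remove rotation
  corr_com <- drift_correct(rot, method = "com")
  spread_com <- tapply(corr_com$x_corr_um, corr_com$particle_id, sd)
  expect_gt(max(spread_com), 1e-3)
})

test_that("a single particle with zero drift is its own COM", {
  one <- tibble::tibble(particle_id = "p1", frame = 1:10,
                        t_s = (0:9) / 100,
                        x_um = 3 + cumsum(rep(0.01, 10)),
                        y_um = 2, diameter_um = 1, intensity = 50)
  corr <- suppressWarnings(drift_correct(one))
  expect_true(all(abs(corr$x_corr_um) < 1e-12))
  expect_true(all(abs(corr$y_corr_um) < 1e-12))
})

test_that("drift-corrected drifting truth matches the free truth", {
  free <- cached_fixture("free_jurkat_like", render = FALSE)$truth
  drif <- cached_fixture("drifting", render = FALSE)$truth
  cf <- drift_correct(free)
  cd <- drift_correct(drif)
  expect_equal(cd$x_corr_um, cf$x_corr_um, tolerance = 1e-8)
  expect_equal(cd$y_corr_um, cf$y_corr_um, tolerance = 1e-8)
})

test_that("corrected MSD is invariant under an injected rigid motion", {
  free <- cached_fixture("free_jurkat_like", render = FALSE)$truth
  moved <- dplyr::mutate(free, th = 0.002 * (frame - 1),
                         xr = cos(th) * x_um - sin(th) * y_um +
                           0.1 * (frame - 1) / 512,
                         yr = sin(th) * x_um + cos(th) * y_um,
                         x_um = xr, y_um = yr)
  moved <- dplyr::select(moved, -th, -xr, -yr)
  m0 <- ensemble_msd(compute_msd(drift_correct(free), lags = c(1, 4, 16)))
  m1 <- ensemble_msd(compute_msd(drift_correct(moved), lags = c(1, 4, 16)))
  expect_true(all(abs(m1$msd_um2 - m0$msd_um2) <
                    3 * sqrt(m0$se^2 + m1$se^2) + 1e-12))
})
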