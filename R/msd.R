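#' Time-averaged mean squared displacement
#'
#' For each trajectory computes
#' `MSD(tau_k) = mean_j ||r(t_j + tau_k) - r(t_j)||^2` over all
#' overlapping time origins `j` (set `overlapping = FALSE` for
#' independent, non-overlapping origins). Drift-corrected positions
#' (`x_corr_um`, `y_corr_um`) are used when present, raw positions
#' otherwise.
#'
#' @param traj Trajectory tibble with contiguous frames per particle.
#' @param max_lag_fraction Largest lag as a fraction of trajectory
#'   length. Default 0.25.
#' @param lags Optional integer vector of lags (frames), overriding
#'   `max_lag_fraction`.
#' @param overlapping Use all overlapping origins (default) or
#'   non-overlapping ones.
#' @param min_length Minimum trajectory length, frames. Default 8.
#' @return Tibble of class `ptmr_msd`: `nucleus_id` (if present),
#'   `particle_id`, `lag_s`, `msd_um2`, `n_origins`. Attributes: `dt_s`
#'   and `particles`, a per-particle tibble with the time-mean optical
#'   radius `R_um`, mean intensity and length used downstream.
#' @examples
#' tr <- tibble::tibble(particle_id = "p1", frame = 1:3,
#'                      x_um = c(0, 1, 1), y_um = c(0, 0, 1))
#' compute_msd(tr, max_lag_fraction = 1, min_length = 3)
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25, lags = NULL,
                        overlapping = TRUE, min_length = 8) {
  stopifnot(all(c("particle_id", "frame") %in% names(traj)))
  xcol <- if ("x_corr_um" %in% names(traj)) "x_corr_um" else "x_um"
  ycol <- if ("y_corr_um" %in% names(traj)) "y_corr_um" else "y_um"
  dt <- attr(traj, "dt_s")
  if (is.null(dt)) {
    if ("t_s" %in% names(traj)) {
      dts <- diff(sort(unique(traj$t_s)))
      dt <- min(dts[dts > 0])
    } else dt <- 1
  }

  one <- function(d) {
    d <- arrange(d, .data$frame)
    n <- nrow(d)
    if (n < min_length)
      abort(sprintf("Trajectory %s too short (%d < %d frames).",
                    d$particle_id[1], n, min_length))
    if (any(diff(d$frame) != 1))
      abort(sprintf("Trajectory %s has frame gaps.", d$particle_id[1]))
    ks <- lags %||% seq_len(max(1L, floor(max_lag_fraction * n)))
    ks <- ks[ks >= 1 & ks <= n - 1]
    if (!length(ks))
      abort(sprintf("No valid lags for trajectory %s.", d$particle_id[1]))
    x <- d[[xcol]]; y <- d[[ycol]]
    res <- map(ks, function(k) {
      or <- if (overlapping) seq_len(n - k) else seq(1, n - k, by = k)
      sq <- (x[or + k] - x[or])^2 + (y[or + k] - y[or])^2
      c(msd = mean(sq), n = length(or))
    })
    tibble(particle_id = d$particle_id[1],
           lag_s = ks * dt,
           msd_um2 = map_dbl(res, "msd"),
           n_origins = as.integer(map_dbl(res, "n")))
  }

  parts <- split(traj, traj$particle_id)
  out <- list_rbind(map(parts, one))
  if ("nucleus_id" %in% names(traj)) {
    ids <- distinct(traj, .data$particle_id, .data$nucleus_id)
    out <- left_join(out, ids, by = "particle_id") |>
      select("nucleus_id", dplyr::everything())
  }
  meta <- map(parts, function(d) {
    tibble(particle_id = d$particle_id[1],
           R_um = if ("diameter_um" %in% names(d))
             mean(d$diameter_um) / 2 else NA_real_,
           mean_intensity = if ("intensity" %in% names(d))
             mean(d$intensity) else NA_real_,
           n_frames = nrow(d))
  })
  attr(out, "particles") <- list_rbind(meta)
  attr(out, "dt_s") <- dt
  class(out) <- c("ptmr_msd", class(out))
  out
}

#' Ensemble-averaged MSD across particles
#'
#' @param msd A `ptmr_msd` tibble.
#' @return Tibble `lag_s`, `msd_um2` (mean over particles), `se`
#'   (standard error over particles), `n_particles`.
#' @export
ensemble_msd <- function(msd) {
  msd |>
    group_by(.data$lag_s) |>
    summarise(se = sd(.data$msd_um2) / sqrt(dplyr::n()),
              msd_um2 = mean(.data$msd_um2),
              n_particles = dplyr::n(), .groups = "drop") |>
    select("lag_s", "msd_um2", "se", "n_particles")
}

#' Short-lag free-diffusion fit
#'
#' Fits the 2D free-diffusion law `MSD = 4 D tau` through the origin by
#' weighted least squares (weights = number of origins per lag) over the
#' short-lag window where the motion is free. A negative fitted slope is
#' clamped to `D_eff = 0` and flagged.
#'
#' @param msd A `ptmr_msd` tibble from [compute_msd()].
#' @param max_lag_s Upper end of the fit window, seconds. Default 0.1.
#' @param min_lags Minimum lags required in the window. Default 4.
#' @return A `diffusion_fit` tibble: `particle_id`, `D_eff_um2_s`,
#'   `D_se`, `R_um`, `mean_intensity`, `n_lags`, `flag`.
#' @export
fit_diffusion <- function(msd, max_lag_s = 0.1, min_lags = 4) {
  meta <- attr(msd, "particles")
  one <- function(d) {
    w <- filter(d, .data$lag_s <= max_lag_s)
    if (nrow(w) < min_lags)
      abort(sprintf(
        "Only %d lag(s) <= %g s for trajectory %s (need >= %d).",
        nrow(w), max_lag_s, d$particle_id[1], min_lags))
    wt <- w$n_origins
    D <- sum(wt * w$lag_s * w$msd_um2) / (4 * sum(wt * w$lag_s^2))
    flag <- NA_character_
    if (D < 0) { D <- 0; flag <- "negative_slope" }
    resid <- w$msd_um2 - 4 * D * w$lag_s
    # slope variance of a weighted through-origin fit, residual-based
    se <- if (nrow(w) > 1 && D > 0)
      sqrt((sum(wt * resid^2) / (nrow(w) - 1)) / sum(wt * w$lag_s^2)) / 4
    else NA_real_
    tibble(particle_id = d$particle_id[1], D_eff_um2_s = D, D_se = se,
           n_lags = nrow(w), flag = flag)
  }
  out <- list_rbind(map(split(msd, msd$particle_id), one))
  if (!is.null(meta))
    out <- left_join(out, select(meta, "particle_id", "R_um",
                                 "mean_intensity"), by = "particle_id")
  class(out) <- c("diffusion_fit", class(out))
  out
}

#' Anomalous diffusion exponent
#'
#' Least-squares slope of `log MSD` versus `log tau` over a lag window:
#' alpha = 1 for free diffusion, < 1 for confined/subdiffusive motion,
#' > 1 for directed/superdiffusive motion. Zero MSD values are excluded.
#'
#' @param msd A `ptmr_msd` tibble.
#' @param lag_range_s Length-2 window `c(lo, hi)` in seconds; default
#'   the full lag range.
#' @return Tibble `particle_id`, `alpha`, `alpha_se`, `n_lags`.
#' @export
fit_anomalous_exponent <- function(msd, lag_range_s = NULL) {
  one <- function(d) {
    if (!is.null(lag_range_s))
      d <- filter(d, .data$lag_s >= lag_range_s[1],
                  .data$lag_s <= lag_range_s[2])
    d <- filter(d, .data$msd_um2 > 0)
    if (nrow(d) < 3)
      abort(sprintf("Fewer than 3 usable lags for trajectory %s.",
                    d$particle_id[1]))
    f <- lm(log(msd_um2) ~ log(lag_s), data = d)
    tibble(particle_id = d$particle_id[1],
           alpha = unname(coef(f)[2]),
           alpha_se = summary(f)$coefficients[2, 2],
           n_lags = nrow(d))
  }
  list_rbind(map(split(msd, msd$particle_id), one))
}

#' Apparent viscosity from the Stokes-Einstein relation
#'
#' Inverts `D_eff = kB T / (6 pi eta_app R)` ("sticking" boundary
#' conditions) to `eta_app = kB T / (6 pi D_eff R)` with the optical
#' radius `R` (half the time-mean Gaussian FWHM diameter). `D_eff = 0`
#' yields infinite viscosity, flagged so it can be excluded from
#' averages. Uncertainty on `D_eff` is propagated linearly.
#'
#' @param fits A `diffusion_fit` tibble (or any tibble with
#'   `D_eff_um2_s` and `R_um`), or a numeric vector of diffusivities in
#'   µm²/s (then `R_um` must be given).
#' @param temperature_K Absolute temperature. Default 298.
#' @param R_um Optional radius (µm) overriding the per-particle column.
#' @return Tibble with `eta_app_Pa_s`, `eta_se_Pa_s`, `T_K` and the
#'   input columns; infinite viscosities carry flag
#'   `"zero_diffusivity"`.
#' @examples
#' estimate_viscosity(0.4366, R_um = 0.5, temperature_K = 298) # ~1e-3 Pa s
#' @export
estimate_viscosity <- function(fits, temperature_K = 298, R_um = NULL) {
  if (is.numeric(fits))
    fits <- tibble(particle_id = paste0("d", seq_along(fits)),
                   D_eff_um2_s = as.numeric(fits), D_se = NA_real_)
  stopifnot("D_eff_um2_s" %in% names(fits))
  if (!is.null(R_um)) fits$R_um <- R_um
  if (!"R_um" %in% names(fits))
    abort("`R_um` must be supplied or present in `fits`.")
  if (!"D_se" %in% names(fits)) fits$D_se <- NA_real_
  if (!is.finite(temperature_K) || temperature_K <= 0)
    abort("`temperature_K` must be positive.")
  if (any(fits$R_um <= 0, na.rm = TRUE)) abort("Radii must be positive.")
  if (any(fits$D_eff_um2_s < 0, na.rm = TRUE))
    abort("Diffusivities must be >= 0.")
  out <- fits |>
    mutate(
      T_K = temperature_K,
      eta_app_Pa_s = .kB * temperature_K /
        (6 * pi * (.data$D_eff_um2_s * 1e-12) * (.data$R_um * 1e-6)),
      eta_se_Pa_s = .data$eta_app_Pa_s * .data$D_se / .data$D_eff_um2_s,
      flag = ifelse(.data$D_eff_um2_s == 0, "zero_diffusivity",
                    if ("flag" %in% names(fits)) .data$flag else NA_character_)
    )
  as_tibble(out)
}
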