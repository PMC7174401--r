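# local log-log slope by centred quadratic fit over a sliding window;
# windows are shifted (one-sided) at the ends. Exact for power laws.
local_log_slope <- function(lx, ly, window = 5) {
  n <- length(lx)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    i0 <- max(1, min(i - half, n - window + 1))
    i1 <- min(n, i0 + window - 1)
    idx <- i0:i1
    x <- lx[idx]; y <- ly[idx]
    if (length(unique(x)) >= 3) {
      f <- lm(y ~ x + I(x^2))
      unname(coef(f)[2] + 2 * coef(f)[3] * lx[i])
    } else if (length(unique(x)) == 2) {
      unname(coef(lm(y ~ x))[2])
    } else NA_real_
  }, numeric(1))
}

#' Viscoelastic spectrum from an MSD curve (Mason approximation)
#'
#' Converts a mean-squared-displacement curve into the frequency-dependent
#' shear modulus through the analytic approximation to the generalized
#' Stokes-Einstein relation: at each lag `tau` (frequency
#' `omega = 1/tau`),
#'
#' `Gd(omega) = 2 kB T / (3 pi R MSD(tau) Gamma(1 + alpha(tau)))`
#'
#' where `alpha(tau)` is the local slope of `log MSD` vs `log tau`
#' (centred quadratic over `slope_window` points, one-sided and flagged
#' at the endpoints), and the phase is
#' `delta(omega) = (pi/2) * dlog Gd / dlog omega`, clipped to
#' `[0, pi/2]` (excursions beyond 5% are flagged). Derived quantities:
#' storage modulus `G' = Gd cos delta`, loss modulus
#' `G'' = Gd sin delta`, dynamic viscosity `eta(omega) = G'' / omega`.
#' Points whose local MSD slope falls outside (-0.5, 1.5) are masked
#' (the Gamma correction approaches a pole there).
#'
#' The frequency grid is exactly the reciprocal of the measured lags; no
#' resampling is performed. A direct numerical evaluation of the Laplace
#' transform is available via [gser_laplace()] for cross-checks on
#' analytic inputs.
#'
#' @param msd A `ptmr_msd` tibble ([compute_msd()]), or any tibble with
#'   `particle_id`, `lag_s`, `msd_um2`.
#' @param R_um Probe radius in µm; default taken per particle from the
#'   `particles` attribute (time-mean optical radius).
#' @param temperature_K Absolute temperature. Default 298.
#' @param slope_window Window (points) of the local log-slope estimator.
#'   Default 5.
#' @return Tibble of class `rheology_spectrum`: `particle_id`,
#'   `omega_rad_s`, `lag_s`, `msd_um2`, `alpha_local`, `Gd_Pa`,
#'   `delta_rad`, `Gp_Pa`, `Gpp_Pa`, `eta_Pa_s`, `R_um`, `endpoint`,
#'   `masked`, `flag`.
#' @export
mason_modulus <- function(msd, R_um = NULL, temperature_K = 298,
                          slope_window = 5) {
  stopifnot(all(c("particle_id", "lag_s", "msd_um2") %in% names(msd)))
  meta <- attr(msd, "particles")
  kT <- .kB * temperature_K

  one <- function(d) {
    d <- arrange(d, .data$lag_s) |> filter(.data$msd_um2 > 0)
    if (nrow(d) < max(3, slope_window))
      abort(sprintf("Too few positive MSD points for %s.", d$particle_id[1]))
    R <- if (!is.null(R_um)) R_um
      else if (!is.null(meta)) meta$R_um[match(d$particle_id[1], meta$particle_id)]
      else NA_real_
    if (!is.finite(R) || R <= 0)
      abort("Probe radius unavailable; pass `R_um`.")
    lt <- log(d$lag_s); lm_ <- log(d$msd_um2)
    alpha <- local_log_slope(lt, lm_, slope_window)
    masked <- !is.finite(alpha) | alpha <= -0.5 | alpha >= 1.5
    Gd <- 2 * kT / (3 * pi * (R * 1e-6) * (d$msd_um2 * 1e-12) *
                      gamma(1 + pmax(pmin(alpha, 1.499), -0.499)))
    Gd[masked] <- NA_real_
    # phase from the log-slope of Gd along increasing omega
    omega <- 1 / d$lag_s
    ord <- order(omega)
    slope_g <- rep(NA_real_, nrow(d))
    ok <- ord[is.finite(Gd[ord]) & Gd[ord] > 0]
    if (length(ok) >= 3)
      slope_g[ok] <- local_log_slope(log(omega[ok]), log(Gd[ok]), slope_window)
    delta <- (pi / 2) * slope_g
    excur <- !is.na(delta) &
      (delta < -0.05 * pi / 2 | delta > (1 + 0.05) * pi / 2)
    delta <- pmin(pmax(delta, 0), pi / 2)
    n <- nrow(d)
    endpoint <- seq_len(n) <= (slope_window - 1) %/% 2 |
      seq_len(n) > n - (slope_window - 1) %/% 2
    tibble(particle_id = d$particle_id[1],
           omega_rad_s = omega, lag_s = d$lag_s, msd_um2 = d$msd_um2,
           alpha_local = alpha, Gd_Pa = Gd, delta_rad = delta,
           Gp_Pa = Gd * cos(delta), Gpp_Pa = Gd * sin(delta),
           eta_Pa_s = Gd * sin(delta) / omega,
           R_um = R, endpoint = endpoint, masked = masked,
           flag = ifelse(excur, "phase_excursion", NA_character_)) |>
      arrange(.data$omega_rad_s)
  }
  out <- list_rbind(map(split(msd, msd$particle_id), one))
  attr(out, "temperature_K") <- temperature_K
  class(out) <- c("rheology_spectrum", class(out))
  out
}

#' Direct Laplace-domain generalized Stokes-Einstein evaluation
#'
#' Numerical cross-check of the analytic (Mason) shortcut: evaluates the
#' magnitude of the shear modulus at Laplace frequency `s = 1/tau` from
#' the numerically Laplace-transformed MSD,
#' `G(s) = kB T / (pi R s <r~^2(s)>)` up to the dimensional convention
#' of the 2D MSD (a factor 3/2 relative to the Mason form is applied so
#' both agree on power-law inputs). Intended for validation on smooth
#' analytic MSDs, not for routine analysis.
#'
#' @param msd Tibble with `lag_s`, `msd_um2` for one particle.
#' @param R_um Probe radius, µm.
#' @param temperature_K Temperature, K.
#' @param s_values Laplace frequencies (1/s); default reciprocal interior
#'   lags.
#' @return Tibble `s`, `G_Pa`.
#' @export
gser_laplace <- function(msd, R_um, temperature_K = 298, s_values = NULL) {
  d <- arrange(msd, .data$lag_s)
  s_values <- s_values %||%
    (1 / d$lag_s[d$lag_s > min(d$lag_s) & d$lag_s < max(d$lag_s)])
  kT <- .kB * temperature_K
  # trapezoidal Laplace transform of the MSD over the measured window
  G <- map_dbl(s_values, function(s) {
    f <- d$msd_um2 * 1e-12 * exp(-s * d$lag_s)
    lt <- sum(diff(d$lag_s) * (head(f, -1) + tail(f, -1)) / 2)
    (2 / 3) * kT / (pi * (R_um * 1e-6) * s * lt)
  })
  tibble(s = s_values, G_Pa = G)
}

#' Kelvin-Voigt summary of a viscoelastic spectrum
#'
#' Summarises a [mason_modulus()] spectrum as a Voigt body (elastic
#' spring of rigidity G' in parallel with a dashpot of viscosity eta).
#' Each element is read off in the frequency limit where it dominates
#' and the Mason approximation is accurate: the plateau rigidity is the
#' median of `G'(omega)` over the flat points (local log-slope of G'
#' below 0.2 in magnitude) within the bottom half-decade of frequencies,
#' and the viscosity is the mean of `eta(omega)` over the top
#' half-decade — the high-frequency limit that should match the
#' apparent viscosity from the diffusive MSD regime. (Restricting the
#' plateau read-out to low frequencies matters because the analytic
#' approximation overestimates G' around the crossover `omega ~ 1/tau_r`
#' even though G' of a true Voigt body is flat everywhere.) Also reports
#' the loss/storage ratio over the flat region. Spectra without a flat
#' region keep their overall median G' with a `non_plateau` flag.
#'
#' @param spec A `rheology_spectrum` tibble.
#' @param flatness Maximum |log-slope| of G' for a point to count as
#'   plateau. Default 0.2.
#' @return A `voigt_fit` tibble: `particle_id`, `Gp_Pa`, `eta_Pa_s`,
#'   `Gpp_over_Gp`, `n_flat`, `non_plateau`.
#' @export
fit_voigt <- function(spec, flatness = 0.2) {
  one <- function(d) {
    d <- arrange(filter(d, !.data$masked, is.finite(.data$Gd_Pa)),
                 .data$omega_rad_s)
    if (nrow(d) < 3 ||
        max(d$omega_rad_s) / min(d$omega_rad_s) < 10)
      abort(sprintf("Spectrum of %s spans less than one decade.",
                    d$particle_id[1]))
    pos <- d$Gp_Pa > 0
    slope <- rep(NA_real_, nrow(d))
    if (sum(pos) >= 3)
      slope[pos] <- local_log_slope(log(d$omega_rad_s[pos]),
                                    log(d$Gp_Pa[pos]), 5)
    flat <- !is.na(slope) & abs(slope) < flatness
    non_plateau <- !any(flat)
    lo <- d$omega_rad_s <= min(d$omega_rad_s) * sqrt(10)
    Gp <- if (non_plateau) median(d$Gp_Pa)
      else if (any(flat & lo)) median(d$Gp_Pa[flat & lo])
      else median(d$Gp_Pa[flat])
    hi <- d$omega_rad_s >= max(d$omega_rad_s) / sqrt(10)
    eta <- mean(d$eta_Pa_s[hi], na.rm = TRUE)
    ratio <- if (non_plateau) NA_real_
      else median(d$Gpp_Pa[flat] / d$Gp_Pa[flat])
    tibble(particle_id = d$particle_id[1], Gp_Pa = Gp, eta_Pa_s = eta,
           Gpp_over_Gp = ratio, n_flat = sum(flat),
           non_plateau = non_plateau)
  }
  out <- list_rbind(map(split(spec, spec$particle_id), one))
  class(out) <- c("voigt_fit", class(out))
  out
}
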