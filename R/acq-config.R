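#' Acquisition configuration
#'
#' Describes how a time-lapse stack was (or is to be) acquired: physical
#' pixel size, sampling frequency, recording duration, field of view and
#' absolute temperature. Defaults reproduce a fast phase-contrast recording
#' of an isolated nucleus: 50 nm pixels, 512 Hz sampling for 10 s
#' (5120 frames) at 298 K.
#'
#' @param pixel_size_um Physical size of one pixel, micrometres. Default 0.05.
#' @param frame_rate_hz Sampling frequency, frames per second. Default 512.
#' @param duration_s Recording duration, seconds. Default 10.
#' @param image_shape Integer vector `c(rows, cols)` of the field of view in
#'   pixels. Default `c(512, 512)`.
#' @param temperature_K Absolute temperature, kelvin. Default 298.
#' @param seed Optional integer master seed for any simulation drawing from
#'   this configuration.
#'
#' @return An object of class `acq_config`: a named list with the fields
#'   above plus `n_frames = round(frame_rate_hz * duration_s)` and
#'   `dt_s = 1 / frame_rate_hz`.
#' @examples
#' cfg <- acq_config()
#' cfg$n_frames   # 5120
#' @export
acq_config <- function(pixel_size_um = 0.05,
                       frame_rate_hz = 512,
                       duration_s = 10,
                       image_shape = c(512L, 512L),
                       temperature_K = 298,
                       seed = NULL) {
  stopifnot(length(pixel_size_um) == 1, length(frame_rate_hz) == 1,
            length(duration_s) == 1, length(image_shape) == 2,
            length(temperature_K) == 1)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    abort("`pixel_size_um` must be a positive finite number.")
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    abort("`frame_rate_hz` must be a positive finite number.")
  if (!is.finite(duration_s) || duration_s <= 0)
    abort("`duration_s` must be a positive finite number.")
  if (any(!is.finite(image_shape)) || any(image_shape < 8))
    abort("`image_shape` must be two finite pixel counts >= 8.")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    abort("`temperature_K` must be a positive finite number.")
  structure(
    list(
      pixel_size_um = pixel_size_um,
      frame_rate_hz = frame_rate_hz,
      duration_s = duration_s,
      image_shape = as.integer(image_shape),
      temperature_K = temperature_K,
      seed = if (!is.null(seed)) as.integer(seed) else NULL,
      n_frames = as.integer(round(frame_rate_hz * duration_s)),
      dt_s = 1 / frame_rate_hz
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n")
  cat(sprintf("  pixel size : %g um\n", x$pixel_size_um))
  cat(sprintf("  frame rate : %g Hz (dt = %.5g s)\n", x$frame_rate_hz, x$dt_s))
  cat(sprintf("  duration   : %g s (%d frames)\n", x$duration_s, x$n_frames))
  cat(sprintf("  field      : %d x %d px\n", x$image_shape[1], x$image_shape[2]))
  cat(sprintf("  temperature: %g K\n", x$temperature_K))
  invisible(x)
}

#' Motion models for granule simulation
#'
#' Constructors for the three motion models used by
#' [simulate_trajectories()]:
#'
#' * `motion_free(D)` — free 2D Brownian motion; per-axis increments are
#'   independent Gaussians with variance `2 * D * dt`.
#' * `motion_confined(D, tau_r)` — confined motion in a Kelvin-Voigt
#'   medium, simulated as an exact-discretisation Ornstein-Uhlenbeck
#'   process with relaxation time `tau_r` (seconds); the stationary MSD
#'   plateau is `4 * D * tau_r` (2D).
#' * `motion_drifting(D, v_um_s)` — free motion plus a rigid drift
#'   `v_um_s` (µm/s, length-2 vector) applied identically to every
#'   particle.
#'
#' @param D Diffusion coefficient, µm²/s (non-negative).
#' @param tau_r Relaxation time of the confining Voigt body, seconds
#'   (positive). For a tracer of radius R in a medium of rigidity G' and
#'   viscosity eta, `tau_r = eta / G'`.
#' @param v_um_s Drift velocity vector `c(vx, vy)`, µm/s.
#' @return An object of class `motion_model`.
#' @examples
#' motion_free(0.1)
#' motion_confined(0.1, tau_r = 0.05)
#' motion_drifting(0.1, c(0.2, -0.1))
#' @export
motion_free <- function(D) {
  check_D(D)
  structure(list(kind = "free", D = D), class = "motion_model")
}

#' @rdname motion_free
#' @export
motion_confined <- function(D, tau_r) {
  check_D(D)
  if (!is.finite(tau_r) || tau_r <= 0)
    abort("`tau_r` must be a positive finite number.")
  structure(list(kind = "confined", D = D, tau_r = tau_r),
            class = "motion_model")
}

#' @rdname motion_free
#' @export
motion_drifting <- function(D, v_um_s) {
  check_D(D)
  if (length(v_um_s) != 2 || any(!is.finite(v_um_s)))
    abort("`v_um_s` must be a finite length-2 velocity vector (um/s).")
  structure(list(kind = "drifting", D = D, v = as.numeric(v_um_s)),
            class = "motion_model")
}

check_D <- function(D) {
  if (length(D) != 1 || !is.finite(D) || D < 0)
    abort("Diffusion coefficient `D` must be a single finite number >= 0.")
  invisible(D)
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model: %s> D = %g um^2/s", x$kind, x$D))
  if (x$kind == "confined") cat(sprintf(", tau_r = %g s", x$tau_r))
  if (x$kind == "drifting")
    cat(sprintf(", v = (%g, %g) um/s", x$v[1], x$v[2]))
  cat("\n")
  invisible(x)
}
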