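#' Deterministic synthetic fixtures
#'
#' Builds one of three named, fully reproducible test beds emulating a
#' fast phase-contrast recording of chromatin granules in one nucleus:
#'
#' * `"free_jurkat_like"` — 12 granules in free Brownian motion
#'   (D = 0.1 µm²/s) recorded at 512 Hz for 10 s (5120 frames).
#' * `"confined_voigt"` — the same acquisition with confined
#'   Ornstein-Uhlenbeck motion (tau_r = 0.05 s), the tracer picture of a
#'   Kelvin-Voigt medium.
#' * `"drifting"` — free motion plus a rigid drift of the whole field
#'   (0.2, 0.1) µm/s; identical particle streams to `"free_jurkat_like"`,
#'   so after perfect drift subtraction the two fixtures coincide.
#'
#' Each preset carries a fixed seed: calling `make_fixture()` twice with
#' the same arguments returns bit-identical stacks. Presets render on a
#' 256 x 256 px field (50 nm pixels); pass `duration_s`, `image_shape` or
#' `n_particles` to scale a preset down (e.g. for fast tests) without
#' changing its physics.
#'
#' @param name One of `"free_jurkat_like"`, `"confined_voigt"`,
#'   `"drifting"`.
#' @param dir Optional directory; when given, the stack (`<name>.tif`),
#'   ground truth (`<name>_truth.csv`) and configuration
#'   (`<name>_config.yaml`) are written there.
#' @param duration_s,image_shape,n_particles Optional overrides of the
#'   preset acquisition.
#' @param render Render the image stack? With `FALSE` only trajectories
#'   are simulated (`stack` is `NULL`); useful when only ground truth is
#'   needed, since rendering full-length presets is memory-hungry.
#' @param noise Add background noise at peak SNR ~ 10? Default `TRUE`.
#' @return A list with elements `stack` ([image_stack()] or `NULL`),
#'   `truth` (see [simulate_trajectories()]) and `config`
#'   ([acq_config()]).
#' @examples
#' fx <- make_fixture("confined_voigt", duration_s = 0.05, render = FALSE)
#' attr(fx$truth, "model")$tau_r
#' @export
make_fixture <- function(name, dir = NULL,
                         duration_s = NULL, image_shape = NULL,
                         n_particles = NULL, render = TRUE, noise = TRUE) {
  presets <- list(
    free_jurkat_like = list(model = motion_free(0.1), seed = 101L),
    confined_voigt   = list(model = motion_confined(0.1, tau_r = 0.05), seed = 101L),
    drifting         = list(model = motion_drifting(0.1, c(0.2, 0.1)), seed = 101L)
  )
  if (length(name) != 1 || !name %in% names(presets))
    abort(sprintf("Unknown preset '%s'. Presets: %s", name,
                  paste(names(presets), collapse = ", ")))
  p <- presets[[name]]
  config <- acq_config(
    pixel_size_um = 0.05,
    frame_rate_hz = 512,
    duration_s = duration_s %||% 10,
    image_shape = image_shape %||% c(256L, 256L),
    temperature_K = 298,
    seed = p$seed
  )
  np <- n_particles %||% 12L

  # keep diffusing particles inside the rendering margin for the whole
  # recording: 3 sigma + expected wander + total drift
  # the drift allowance enters every preset's margin so that all presets
  # draw identical initial positions from the shared seed
  d_max <- 1.5
  min_sep <- 2
  sig_max <- d_max / (2 * sqrt(2 * log(2)))
  wander <- 3 * sqrt(2 * p$model$D * config$duration_s)
  drift_len <- sqrt(sum(c(0.2, 0.1)^2)) * config$duration_s
  margin <- 3 * sig_max + wander + drift_len
  # the margin must leave room to place all particles at min_sep: cap it
  # so the free box spans a loose ceiling(sqrt(np)) grid of spacing
  # min_sep (long recordings therefore cannot guarantee containment on
  # this field; truth-only use is unaffected, rendering such a recording
  # errors explicitly in render_stack())
  field <- min(config$image_shape * config$pixel_size_um)
  span_needed <- (ceiling(sqrt(np)) - 1) * min_sep * 1.5
  max_margin <- max(0, (field - span_needed) / 2)
  capped <- margin > min(max_margin, 0.45 * field)
  margin <- min(margin, max_margin, 0.45 * field)
  if (capped && render)
    warn(paste0(
      "Recording too long for guaranteed containment on this field; ",
      "rendering may fail if a particle wanders out. Shorten ",
      "`duration_s`, enlarge `image_shape`, or use `render = FALSE`."))

  truth <- simulate_trajectories(np, p$model, config,
                                 diameter_range_um = c(0.5, d_max),
                                 margin_um = margin,
                                 min_separation_um = min_sep)
  stack <- NULL
  if (render) {
    noise_sd <- if (noise) mean(truth$intensity) / 10 else 0
    stack <- render_stack(truth, config, background = 100,
                          noise_sd = noise_sd, seed = p$seed + 1L)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!is.null(stack)) write_stack(stack, file.path(dir, paste0(name, ".tif")))
    readr::write_csv(
      select(as_tibble(truth), "nucleus_id", "particle_id", "frame",
             "x_um", "y_um", "diameter_um", "intensity"),
      file.path(dir, paste0(name, "_truth.csv")))
    yaml::write_yaml(unclass(config)[c("pixel_size_um", "frame_rate_hz",
                                       "duration_s", "image_shape",
                                       "temperature_K", "seed")],
                     file.path(dir, paste0(name, "_config.yaml")))
  }
  list(stack = stack, truth = truth, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
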