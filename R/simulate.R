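#' Simulate ground-truth granule trajectories
#'
#' Draws `n_particles` independent 2D trajectories under a [motion
#' model][motion_free] at the sampling defined by an [acq_config()].
#' Free motion uses exact Gaussian increments (per-axis variance
#' `2 D dt`); confined motion uses the exact discretisation of the
#' Ornstein-Uhlenbeck process (update `u' = u exp(-dt/tau_r) + xi` with
#' `xi ~ N(0, D tau_r (1 - exp(-2 dt/tau_r)))`, started from the
#' stationary distribution so the analytic MSD
#' `4 D tau_r (1 - exp(-tau/tau_r))` holds from the first lag); drifting
#' motion adds the same `v * dt` displacement to every particle in every
#' frame.
#'
#' Each particle consumes its own deterministic random streams (one for
#' properties and initial position, one for increments) derived from the
#' master seed, so particle *i* does not depend on how many other
#' particles were simulated — except its placement when
#' `min_separation_um` forces rejection resampling against earlier
#' particles.
#'
#' @param n_particles Number of particles (>= 1).
#' @param model A [motion model][motion_free].
#' @param config An [acq_config()]. Its `seed` (if set) makes the
#'   simulation reproducible.
#' @param diameter_range_um Range the true optical diameters (Gaussian
#'   FWHM, µm) are drawn from, uniform. Default `c(0.5, 1.5)`, the size
#'   class of chromatin granules retained for analysis.
#' @param intensity_range Range of true peak intensities (arbitrary
#'   units), uniform. Default `c(800, 1200)`.
#' @param margin_um Initial positions are uniform inside the field of view
#'   inset by this margin (scalar). Default `NULL` = 5 rendering sigmas of
#'   each particle's diameter. Pass a larger value when long recordings
#'   will be rendered, so diffusing particles stay inside the renderable
#'   area.
#' @param min_separation_um Optional minimum distance between initial
#'   particle positions (µm, rejection sampling); `NULL` (default) places
#'   particles uniformly at random. Rendering-oriented fixtures use this
#'   to avoid overlapping spots, which the detector does not deblend.
#' @param nucleus_id Identifier stored in the `nucleus_id` column.
#'
#' @return A tibble of class `ptmr_truth` with one row per particle per
#'   frame: `nucleus_id`, `particle_id`, `frame` (1-based), `t_s`,
#'   `x_um`, `y_um`, `diameter_um`, `intensity` (true peak height).
#'   Attributes: `config`, `model`, and `drift`, a per-frame tibble of the
#'   cumulative rigid drift (`frame`, `dx_um`, `dy_um`) applied to all
#'   particles (zero unless the model drifts).
#' @examples
#' cfg <- acq_config(duration_s = 0.1, seed = 1)
#' tr <- simulate_trajectories(3, motion_free(0.1), cfg)
#' dplyr::count(tr, particle_id)
#' @export
simulate_trajectories <- function(n_particles, model, config = acq_config(),
                                  diameter_range_um = c(0.5, 1.5),
                                  intensity_range = c(800, 1200),
                                  margin_um = NULL,
                                  min_separation_um = NULL,
                                  nucleus_id = "nucleus1") {
  stopifnot(inherits(model, "motion_model"), inherits(config, "acq_config"))
  if (length(n_particles) != 1 || !is.finite(n_particles) || n_particles < 1)
    abort("`n_particles` must be a single integer >= 1.")
  n_particles <- as.integer(n_particles)
  if (any(!is.finite(diameter_range_um)) || any(diameter_range_um <= 0))
    abort("`diameter_range_um` must be positive and finite.")

  n <- config$n_frames
  dt <- config$dt_s
  field_um <- config$image_shape * config$pixel_size_um # c(height, width)

  seeds <- derive_seeds(config$seed, 2L * n_particles)
  prop_seeds <- seeds[seq.int(1L, by = 2L, length.out = n_particles)]
  inc_seeds <- seeds[seq.int(2L, by = 2L, length.out = n_particles)]

  # properties and initial position of particle i come from its own
  # derived stream, so (absent `min_separation_um` rejections) particle i
  # is identical no matter how many other particles are simulated
  d_um <- numeric(n_particles); inten <- numeric(n_particles)
  x0 <- numeric(n_particles); y0 <- numeric(n_particles)
  for (k in seq_len(n_particles)) {
    with_seed(prop_seeds[k], {
      d_um[k] <- runif(1, diameter_range_um[1], diameter_range_um[2])
      inten[k] <- runif(1, intensity_range[1], intensity_range[2])
      sigma <- d_um[k] / (2 * sqrt(2 * log(2)))
      margin <- if (is.null(margin_um)) 5 * sigma else margin_um[1]
      if (2 * margin >= min(field_um))
        abort("Field of view too small for the requested margin; enlarge `image_shape` or reduce `margin_um`.")
      for (try in seq_len(2000)) {
        cx <- runif(1, margin, field_um[2] - margin)
        cy <- runif(1, margin, field_um[1] - margin)
        ok <- is.null(min_separation_um) || k == 1 ||
          all((x0[seq_len(k - 1)] - cx)^2 +
              (y0[seq_len(k - 1)] - cy)^2 >= min_separation_um^2)
        if (ok) break
        if (try == 2000)
          abort("Could not place particles at the requested separation.")
      }
      x0[k] <- cx; y0[k] <- cy
    })
  }
  props <- list(diameter = d_um, intensity = inten, x0 = x0, y0 = y0)

  # cumulative collective drift, identical for all particles
  drift <- if (model$kind == "drifting") {
    tibble(frame = seq_len(n),
           dx_um = model$v[1] * dt * (seq_len(n) - 1),
           dy_um = model$v[2] * dt * (seq_len(n) - 1))
  } else {
    tibble(frame = seq_len(n), dx_um = 0, dy_um = 0)
  }

  one_particle <- function(i) {
    with_seed(inc_seeds[i], {
      x0 <- props$x0[i]
      y0 <- props$y0[i]
      xy <- switch(model$kind,
        free = ,
        drifting = {
          sdstep <- sqrt(2 * model$D * dt)
          cbind(x0 + c(0, cumsum(rnorm(n - 1, 0, sdstep))),
                y0 + c(0, cumsum(rnorm(n - 1, 0, sdstep))))
        },
        confined = {
          a <- exp(-dt / model$tau_r)
          sd_stat <- sqrt(model$D * model$tau_r)
          sd_step <- sqrt(model$D * model$tau_r * (1 - a^2))
          u <- matrix(0, n, 2)
          u[1, ] <- rnorm(2, 0, sd_stat)
          if (n > 1) {
            xi <- matrix(rnorm(2 * (n - 1), 0, sd_step), n - 1, 2)
            for (k in 2:n) u[k, ] <- u[k - 1, ] * a + xi[k - 1, ]
          }
          cbind(x0 + u[, 1], y0 + u[, 2])
        }
      )
      tibble(
        nucleus_id = nucleus_id,
        particle_id = paste0("p", sprintf("%03d", i)),
        frame = seq_len(n),
        t_s = (seq_len(n) - 1) * dt,
        x_um = xy[, 1] + drift$dx_um,
        y_um = xy[, 2] + drift$dy_um,
        diameter_um = props$diameter[i],
        intensity = props$intensity[i]
      )
    })
  }

  out <- list_rbind(map(seq_len(n_particles), one_particle))
  if (any(!is.finite(out$x_um)) || any(!is.finite(out$y_um)))
    abort("Simulation produced non-finite positions; check model parameters.")
  attr(out, "config") <- config
  attr(out, "model") <- model
  attr(out, "drift") <- drift
  class(out) <- c("ptmr_truth", class(out))
  out
}

# Deterministic child seeds from one master seed (all < 2^31). Drawn
# with replacement so the first k seeds do not depend on how many are
# requested (prefix stability across particle counts). When the master
# is NULL the current RNG state is used and results are not
# reproducible across calls.
derive_seeds <- function(master, k) {
  if (is.null(master)) return(rep(NA_integer_, k))
  with_seed(master, sample.int(.Machine$integer.max, k, replace = TRUE))
}

# Evaluate `expr` under a temporary RNG state; NA seed = use current RNG.
with_seed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
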