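#' Plot drift-corrected trajectories
#'
#' One path per particle in the plane of the nucleus, drift-corrected
#' positions when available.
#'
#' @param traj Trajectory tibble.
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj) {
  xcol <- if ("x_corr_um" %in% names(traj)) "x_corr_um" else "x_um"
  ycol <- if ("y_corr_um" %in% names(traj)) "y_corr_um" else "y_um"
  ggplot2::ggplot(traj, ggplot2::aes(.data[[xcol]], .data[[ycol]],
                                     colour = .data$particle_id)) +
    ggplot2::geom_path(show.legend = FALSE, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Granule trajectories") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories MSD band: per-particle curves plus the
#'   ensemble mean, log-log, with a slope-1 guide.
#' @param object,x Result object.
#' @param ... Unused.
#' @export
autoplot.ptmr_msd <- function(object, ...) {
  ens <- ensemble_msd(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$lag_s, .data$msd_um2,
                               group = .data$particle_id)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = ens, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 0.9) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression(MSD ~ (mu * m^2)),
                  title = "Mean squared displacement") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories Viscoelastic spectrum: G', G'' and
#'   eta(omega) versus frequency, log-log.
#' @export
autoplot.rheology_spectrum <- function(object, ...) {
  d <- filter(object, !.data$masked) |>
    tidyr::pivot_longer(c("Gp_Pa", "Gpp_Pa", "eta_Pa_s"),
                        names_to = "quantity", values_to = "value") |>
    filter(.data$value > 0)
  labs <- c(Gp_Pa = "G' (Pa)", Gpp_Pa = "G'' (Pa)",
            eta_Pa_s = "η(ω) (Pa s)")
  ggplot2::ggplot(d, ggplot2::aes(.data$omega_rad_s, .data$value,
                                  colour = labs[.data$quantity],
                                  group = interaction(.data$particle_id,
                                                      .data$quantity))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(omega ~ (rad / s)), y = NULL,
                  colour = NULL, title = "Viscoelastic spectrum") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories Apparent-viscosity distribution across
#'   particles of each nucleus.
#' @param fits Viscosity tibble from [estimate_viscosity()].
#' @export
plot_viscosity <- function(fits) {
  d <- filter(fits, is.finite(.data$eta_app_Pa_s))
  ggplot2::ggplot(d, ggplot2::aes(.data$eta_app_Pa_s)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(eta[app] ~ (Pa %.% s)), y = "granules",
                  title = "Apparent viscosity distribution") +
    ggplot2::theme_minimal()
}
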