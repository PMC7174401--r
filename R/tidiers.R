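#' Tidy and summarise fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per particle,
#' `glance()` a one-row ensemble summary.
#'
#' @param x A `diffusion_fit` or `voigt_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name ptmr-tidiers
NULL

#' @rdname ptmr-tidiers
#' @export
tidy.diffusion_fit <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname ptmr-tidiers
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(n_particles = nrow(x),
         D_mean_um2_s = mean(x$D_eff_um2_s),
         D_sd_um2_s = sd(x$D_eff_um2_s),
         n_flagged = sum(!is.na(x$flag)))
}

#' @rdname ptmr-tidiers
#' @export
tidy.voigt_fit <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname ptmr-tidiers
#' @export
glance.voigt_fit <- function(x, ...) {
  tibble(n_particles = nrow(x),
         Gp_median_Pa = median(x$Gp_Pa, na.rm = TRUE),
         eta_median_Pa_s = median(x$eta_Pa_s, na.rm = TRUE),
         Gpp_over_Gp = median(x$Gpp_over_Gp, na.rm = TRUE),
         n_non_plateau = sum(x$non_plateau))
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
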