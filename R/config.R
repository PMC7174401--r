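#' Pipeline configuration
#'
#' One validated document holding every tunable of the analysis chain,
#' with units fixed (µm, s, K, Pa). Unknown keys are rejected. The
#' configuration carries a provenance block (package version + content
#' hash) that is written next to every pipeline output.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A named list of class `pipeline_config`.
#' @section Defaults:
#' \describe{
#'   \item{pixel_size_um = 0.05, frame_rate_hz = 512,
#'     temperature_K = 298}{acquisition}
#'   \item{min_contrast = 4, min_separation_px = 3, smooth_sigma = 1,
#'     fit_window_px = NULL, expected_diameter_um = 1,
#'     diameter_min_um = 0.5, diameter_max_um = 1.5}{detection}
#'   \item{max_disp_um = NULL, expected_D_um2_s = 0.5,
#'     use_descriptors = TRUE}{linking}
#'   \item{qc_rules = c("diameter", "intensity"), qc_step_mode =
#'     "change", qc_max_step_change = 0.5, qc_max_size_change = 0.1,
#'     qc_min_length = 64}{quality control; the step-length rule is
#'     available in `qc_rules` but not enabled by default, since it
#'     rejects genuinely Brownian steps (see the methods vignette)}
#'   \item{drift_method = "rigid_com"}{drift correction}
#'   \item{max_lag_fraction = 0.25, fit_max_lag_s = 0.1}{MSD and
#'     diffusion fit}
#'   \item{slope_window = 5}{microrheology log-slope estimator}
#'   \item{min_particles = 10}{phenotype}
#'   \item{seed = NULL}{simulation seed, when the pipeline simulates}
#' }
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    pixel_size_um = 0.05, frame_rate_hz = 512, temperature_K = 298,
    min_contrast = 4, min_separation_px = 3, smooth_sigma = 1,
    fit_window_px = NULL, expected_diameter_um = 1,
    diameter_min_um = 0.5, diameter_max_um = 1.5,
    max_disp_um = NULL, expected_D_um2_s = 0.5, use_descriptors = TRUE,
    qc_rules = c("diameter", "intensity"), qc_step_mode = "change",
    qc_max_step_change = 0.5, qc_max_size_change = 0.1,
    qc_min_length = 64,
    drift_method = "rigid_com",
    max_lag_fraction = 0.25, fit_max_lag_s = 0.1,
    slope_window = 5,
    min_particles = 10,
    seed = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")), class = "ptmr_config_error")
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  cfg$provenance <- list(
    package = "ptmr",
    version = as.character(utils::packageVersion("ptmr")),
    hash = rlang::hash(cfg[sort(names(cfg))])
  )
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip `read_config(write_config(cfg, path))` reproduces the
#' same content hash; unknown keys in the file are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` the path, invisibly; `read_config()` a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$provenance <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>", sprintf("(hash %s)\n", x$provenance$hash))
  flat <- x[setdiff(names(x), "provenance")]
  for (k in names(flat)) {
    v <- flat[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "auto" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
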