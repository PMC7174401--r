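#' Run the full microrheology pipeline
#'
#' Composes the analysis chain detection -> descriptor linking -> quality
#' control -> drift correction -> MSD -> diffusivity and apparent
#' viscosity -> viscoelastic spectra and Voigt summary -> per-nucleus
#' phenotype, logging the counts entering and leaving every filter. The
#' input can be an [image_stack()], a multi-page TIFF path, or a
#' pre-extracted trajectory table (tibble or CSV path with `particle_id`,
#' `frame`, `x_um`, `y_um`, and optionally `diameter_um`, `intensity`),
#' in which case detection and linking are skipped.
#'
#' Stage failures abort with the stage name in the condition message;
#' outputs of completed stages are retained in the error's `partial`
#' field and, when `output_dir` is set, on disk.
#'
#' @param input Stack, TIFF path, trajectory tibble or trajectory CSV
#'   path.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for CSV outputs (`spots.csv`,
#'   `trajectories.csv`, `drift_record.csv`, `msd.csv`, `fits.csv`,
#'   `spectra.csv`, `voigt.csv`, `phenotype.csv`, `filter_log.csv`,
#'   `config.yaml`).
#' @param nucleus_id Identifier for this specimen.
#' @param quiet Suppress progress messages.
#' @return List of class `ptmr_results` with elements `spots`,
#'   `trajectories`, `drift_record`, `msd`, `fits`, `spectra`, `voigt`,
#'   `phenotype`, `filter_log`, `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         output_dir = NULL, nucleus_id = "nucleus1",
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  log <- list()
  note <- function(stage, n_in, n_out, unit) {
    log[[length(log) + 1]] <<- tibble(stage = stage, n_in = n_in,
                                      n_out = n_out, unit = unit)
  }
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cnd <- rlang::error_cnd(
        class = "ptmr_pipeline_error",
        message = sprintf("Pipeline stage '%s' failed: %s",
                          name, conditionMessage(e)),
        partial = res)
      rlang::cnd_signal(cnd)
    })
  }

  traj_in <- NULL
  if (is.character(input) && length(input) == 1) {
    input <- if (grepl("\\.csv$", input, ignore.case = TRUE))
      readr::read_csv(input, show_col_types = FALSE)
    else
      read_stack(input, config$pixel_size_um, config$frame_rate_hz)
  }
  if (inherits(input, "data.frame")) {
    traj_in <- as_tibble(input)
    if (!"diameter_um" %in% names(traj_in)) traj_in$diameter_um <- 1
    if (!"intensity" %in% names(traj_in)) traj_in$intensity <- 1
    if (!"nucleus_id" %in% names(traj_in)) traj_in$nucleus_id <- nucleus_id
    if (!"t_s" %in% names(traj_in))
      traj_in$t_s <- (traj_in$frame - 1) / config$frame_rate_hz
    attr(traj_in, "dt_s") <- 1 / config$frame_rate_hz
  } else if (!inherits(input, "image_stack")) {
    abort("`input` must be an image_stack, a TIFF/CSV path, or a trajectory table.")
  }

  if (is.null(traj_in)) {
    say("Detecting spots in %d frames ...", length(input$frames))
    res$spots <- stage("detection", {
      if (!length(input$frames) ||
          all(vapply(input$frames, function(f) all(f == f[1]), logical(1))))
        abort("Stack is empty or featureless.")
      s <- detect_spots(input, min_contrast = config$min_contrast,
                        min_separation_px = config$min_separation_px,
                        smooth_sigma = config$smooth_sigma,
                        fit_window_px = config$fit_window_px,
                        expected_diameter_um = config$expected_diameter_um,
                        diameter_range_um = NULL)
      n0 <- nrow(s)
      s <- filter_by_diameter(s, config$diameter_min_um,
                              config$diameter_max_um)
      note("diameter_filter", n0, nrow(s), "spots")
      if (!nrow(s)) abort("No spots in the diameter class.")
      s
    })
    say("Linking %d spots ...", nrow(res$spots))
    res$trajectories <- stage("tracking", {
      tr <- track_spots(input, res$spots,
                        max_disp_um = config$max_disp_um,
                        expected_D_um2_s = config$expected_D_um2_s,
                        use_descriptors = config$use_descriptors,
                        nucleus_id = nucleus_id)
      note("linking", nrow(res$spots), nrow(tr), "spot observations")
      tr
    })
  } else {
    res$trajectories <- traj_in
    note("input_trajectories", nrow(traj_in), nrow(traj_in),
         "spot observations")
  }

  say("Quality control ...")
  res$trajectories <- stage("qc", {
    n0 <- dplyr::n_distinct(res$trajectories$particle_id)
    tr <- qc_filter(res$trajectories,
                    rules = config$qc_rules,
                    step_mode = config$qc_step_mode,
                    max_step_change = config$qc_max_step_change,
                    max_size_change = config$qc_max_size_change,
                    min_length = config$qc_min_length)
    note("qc_filter", n0, dplyr::n_distinct(tr$particle_id),
         "trajectories")
    if (!nrow(tr)) abort("No trajectory passed quality control.")
    if (dplyr::n_distinct(tr$particle_id) < 2)
      abort("Drift correction needs >= 2 accepted particles.")
    res$filter_qc_log <- attr(tr, "qc_log")
    tr
  })

  say("Drift correction ...")
  res$trajectories <- stage("drift", {
    tr <- drift_correct(res$trajectories, method = config$drift_method)
    res$drift_record <- attr(tr, "drift_record")
    tr
  })

  say("MSD and diffusivity ...")
  res$msd <- stage("msd", compute_msd(
    res$trajectories, max_lag_fraction = config$max_lag_fraction,
    min_length = config$qc_min_length))
  res$fits <- stage("diffusion_fit", {
    f <- fit_diffusion(res$msd, max_lag_s = config$fit_max_lag_s)
    estimate_viscosity(f, temperature_K = config$temperature_K)
  })

  say("Microrheology ...")
  res$spectra <- stage("rheology", mason_modulus(
    res$msd, temperature_K = config$temperature_K,
    slope_window = config$slope_window))
  res$voigt <- stage("voigt_fit", fit_voigt(res$spectra))

  say("Phenotype ...")
  res$phenotype <- stage("phenotype", {
    ids <- distinct(res$trajectories, .data$particle_id, .data$nucleus_id)
    summarize_nucleus(left_join(res$fits, ids, by = "particle_id"),
                      min_particles = config$min_particles)
  })

  res$filter_log <- list_rbind(log)
  class(res) <- "ptmr_results"
  if (!is.null(output_dir)) write_results(res, output_dir)
  res
}

#' Write pipeline results as CSV files
#'
#' @param results A `ptmr_results` list from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "ptmr_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x))
      readr::write_csv(drop_list_cols(as_tibble(x)), file.path(dir, name))
  }
  w(results$spots, "spots.csv")
  w(results$trajectories, "trajectories.csv")
  w(results$drift_record, "drift_record.csv")
  w(results$msd, "msd.csv")
  w(results$fits, "fits.csv")
  w(results$spectra, "spectra.csv")
  w(results$voigt, "voigt.csv")
  w(results$phenotype, "phenotype.csv")
  w(results$filter_log, "filter_log.csv")
  write_config(results$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

drop_list_cols <- function(x) {
  x[, !vapply(x, is.list, logical(1)), drop = FALSE]
}

#' @export
print.ptmr_results <- function(x, ...) {
  cat("<ptmr_results>\n")
  if (!is.null(x$trajectories))
    cat(sprintf("  %d accepted trajectories, %d spot observations\n",
                dplyr::n_distinct(x$trajectories$particle_id),
                nrow(x$trajectories)))
  if (!is.null(x$phenotype)) {
    cat("  phenotype:\n")
    print(x$phenotype)
  }
  invisible(x)
}
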