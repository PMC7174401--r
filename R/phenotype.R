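#' Per-nucleus mechanical phenotype
#'
#' Aggregates per-particle results of one or more nuclei into phenotype
#' descriptors: mean and sample standard deviation of the apparent
#' viscosity, the optical density (total integrated spot intensity per
#' total spot area, an intensity-derived compactness descriptor), and
#' the mean optical radius. A nucleus needs at least `min_particles`
#' accepted particles to carry phenotyping value (warning below, hard
#' error below 2, where upstream drift correction is undefined).
#'
#' @param results Tibble with one row per accepted particle:
#'   `nucleus_id`, `particle_id`, `eta_app_Pa_s`, `R_um` and
#'   `mean_intensity` (e.g. [estimate_viscosity()] output). Duplicate
#'   particle ids within a nucleus are an error. Particles flagged with
#'   infinite viscosity are excluded.
#' @param min_particles Minimum accepted particles per nucleus.
#'   Default 10.
#' @param area_um2 Optional named vector of nuclear areas (µm²) by
#'   nucleus id, from an external mask.
#' @return Tibble: `nucleus_id`, `n_particles`, `eta_mean_Pa_s`,
#'   `eta_sd_Pa_s`, `optical_density`, `radius_um`, `area_um2`,
#'   `valid` (met `min_particles`?).
#' @export
summarize_nucleus <- function(results, min_particles = 10,
                              area_um2 = NULL) {
  need <- c("nucleus_id", "particle_id", "eta_app_Pa_s", "R_um")
  stopifnot(all(need %in% names(results)))
  if (anyDuplicated(results[c("nucleus_id", "particle_id")]))
    abort("Duplicate particle_id within a nucleus.")
  results <- filter(results, is.finite(.data$eta_app_Pa_s))
  counts <- dplyr::count(results, .data$nucleus_id)
  if (any(counts$n < 2))
    abort("Fewer than 2 accepted particles in at least one nucleus.")
  if (any(counts$n < min_particles))
    warn(sprintf(
      "%d nucleus/nuclei below the %d-particle phenotype minimum.",
      sum(counts$n < min_particles), min_particles))
  out <- results |>
    group_by(.data$nucleus_id) |>
    summarise(
      n_particles = dplyr::n(),
      eta_mean_Pa_s = mean(.data$eta_app_Pa_s),
      eta_sd_Pa_s = sd(.data$eta_app_Pa_s),
      optical_density = if ("mean_intensity" %in% names(results))
        sum(.data$mean_intensity) / sum(pi * .data$R_um^2)
      else NA_real_,
      radius_um = mean(.data$R_um),
      .groups = "drop") |>
    mutate(valid = .data$n_particles >= min_particles)
  out$area_um2 <- if (!is.null(area_um2))
    unname(area_um2[out$nucleus_id]) else NA_real_
  select(out, "nucleus_id", "n_particles", "eta_mean_Pa_s",
         "eta_sd_Pa_s", "optical_density", "radius_um", "area_um2",
         "valid")
}

#' Non-parametric group comparison of nuclear phenotypes
#'
#' Compares a phenotype metric between groups of nuclei with the
#' two-sided Mann-Whitney U test (2 groups) or the Kruskal-Wallis test
#' (3 or more), with midrank handling of ties. The 0.05 significance
#' threshold is applied to the reported label only, never to filter
#' data. No multiple-testing correction is applied by default; set
#' `adjust = "holm"` to add Holm-adjusted p-values when comparing
#' several metrics.
#'
#' @param phenotypes Tibble with one row per nucleus, a `group` column
#'   and the metric column.
#' @param metric Name of the metric column (string). Default
#'   `"eta_mean_Pa_s"`.
#' @param test `"auto"` (default: Mann-Whitney for 2 groups,
#'   Kruskal-Wallis otherwise), `"mann-whitney"` or `"kruskal-wallis"`.
#' @param min_per_group Minimum nuclei per group. Default 3.
#' @return A `group_comparison` tibble (one row): `metric`, `test`,
#'   `statistic`, `p_value`, `significant`, `n_groups`, `n_total`.
#' @examples
#' ph <- tibble::tibble(group = rep(c("a", "b"), each = 3),
#'                      eta_mean_Pa_s = c(1, 2, 3, 4, 5, 6))
#' compare_groups(ph)
#' @export
compare_groups <- function(phenotypes, metric = "eta_mean_Pa_s",
                           test = c("auto", "mann-whitney",
                                    "kruskal-wallis"),
                           min_per_group = 3) {
  test <- arg_match(test)
  stopifnot("group" %in% names(phenotypes), metric %in% names(phenotypes))
  g <- factor(phenotypes$group)
  x <- phenotypes[[metric]]
  if (nlevels(g) < 2) abort("At least 2 groups are required.")
  if (any(table(g) < min_per_group))
    abort(sprintf("Every group needs >= %d nuclei.", min_per_group))
  if (test == "auto")
    test <- if (nlevels(g) == 2) "mann-whitney" else "kruskal-wallis"
  if (test == "mann-whitney" && nlevels(g) != 2)
    abort("Mann-Whitney requires exactly 2 groups.")
  if (length(unique(x)) == 1) {
    out <- tibble(metric = metric, test = test, statistic = 0,
                  p_value = 1, significant = FALSE,
                  n_groups = nlevels(g), n_total = length(x))
    class(out) <- c("group_comparison", class(out))
    return(out)
  }
  res <- if (test == "mann-whitney") {
    suppressWarnings(
      wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
                  alternative = "two.sided"))
  } else {
    kruskal.test(x, g)
  }
  out <- tibble(metric = metric, test = test,
                statistic = unname(res$statistic),
                p_value = res$p.value,
                significant = res$p.value < 0.05,
                n_groups = nlevels(g), n_total = length(x))
  class(out) <- c("group_comparison", class(out))
  out
}
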