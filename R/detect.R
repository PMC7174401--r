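#' Locate candidate granules in a single frame
#'
#' Candidates are local intensity maxima that stand significantly above
#' the background. The background level is estimated as the frame median
#' and the noise scale as the median absolute deviation; a pixel
#' qualifies when the (optionally smoothed) image exceeds
#' `background + min_contrast * noise_sd` and is the maximum of its
#' neighbourhood. Maxima closer than `min_separation_px` are merged,
#' keeping the brighter one.
#'
#' @param frame Numeric matrix (row = y, col = x).
#' @param min_contrast Detection threshold in units of the background
#'   noise sd. Default 4.
#' @param min_separation_px Minimum distance between reported maxima,
#'   pixels. Default 3.
#' @param smooth_sigma Gaussian pre-smoothing sd in pixels applied before
#'   the maximum search (the subsequent fit uses the raw frame). Default
#'   1; 0 disables.
#' @return Tibble with columns `row`, `col`, `value` (raw intensity at
#'   the maximum), possibly empty.
#' @export
detect_candidates <- function(frame, min_contrast = 4,
                              min_separation_px = 3, smooth_sigma = 1) {
  if (!is.matrix(frame) || any(!is.finite(frame)))
    abort("`frame` must be a finite numeric matrix.")
  bg <- median(frame)
  noise <- mad(frame)
  thr <- bg + min_contrast * noise

  sm <- if (smooth_sigma > 0) gaussian_blur(frame, smooth_sigma) else frame
  size <- 2L * as.integer(min_separation_px) + 1L
  dil <- local_max_filter(sm, size)
  is_max <- (sm >= dil) & (sm > thr) & (frame > thr)
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(tibble(row = integer(), col = integer(), value = numeric()))
  out <- tibble(row = idx[, 1], col = idx[, 2],
                value = frame[idx]) |>
    arrange(dplyr::desc(.data$value))
  # greedy non-maximum suppression at min_separation_px
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- which(keep)
    d2 <- (out$row[kept] - out$row[i])^2 + (out$col[kept] - out$col[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  out[keep, ]
}

# grayscale dilation (moving maximum) over a size x size box
local_max_filter <- function(m, size) {
  img <- EBImage::Image(t(m))
  t(EBImage::imageData(EBImage::dilate(img, EBImage::makeBrush(size, "box"))))
}

gaussian_blur <- function(m, sigma) {
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
}

#' Sub-pixel 2D-Gaussian fit of one spot
#'
#' Least-squares fit of `I0 + A * exp(-((x - x0)^2 + (y - y0)^2) /
#' (2 sigma^2))` on a square window around a candidate pixel
#' (Levenberg-Marquardt). The spot's optical diameter is the fitted
#' Gaussian FWHM `2 sqrt(2 log 2) * sigma` and its intensity the
#' integrated area `2 pi sigma^2 * A`.
#'
#' @param frame Numeric matrix.
#' @param row,col Candidate pixel (integer, 1-based).
#' @param window_px Odd window side length; must lie fully inside the
#'   frame.
#' @return One-row tibble `x_px`, `y_px` (sub-pixel, 1-based pixel
#'   coordinates), `sigma_px`, `amplitude`, `offset`, `fit_residual`
#'   (RMS residual / amplitude), `converged`; or a zero-row tibble with a
#'   `reject_reason` attribute when the fit is rejected (non-convergence,
#'   sigma below 0.5 px, or centre drifting out of the window).
#' @export
fit_spot_gaussian <- function(frame, row, col, window_px = 15) {
  w <- (as.integer(window_px) - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  empty <- function(reason) {
    out <- tibble(x_px = numeric(), y_px = numeric(), sigma_px = numeric(),
                  amplitude = numeric(), offset = numeric(),
                  fit_residual = numeric(), converged = logical())
    attr(out, "reject_reason") <- reason
    out
  }
  if (row - w < 1 || row + w > nr || col - w < 1 || col + w > nc)
    return(empty("window outside frame"))
  rows <- (row - w):(row + w)
  cols <- (col - w):(col + w)
  z <- frame[rows, cols]
  X <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(rows, length(rows), length(cols))

  p0 <- c(I0 = min(z), A = max(z) - min(z), x0 = col, y0 = row,
          s = max(1.5, w / 4))
  res_fun <- function(p) {
    as.vector(z - (p[1] + p[2] *
      exp(-((X - p[3])^2 + (Y - p[4])^2) / (2 * p[5]^2))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = res_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(empty("fit failed"))
  p <- fit$par
  s <- abs(p[["s"]])
  if (!fit$info %in% 1:4) return(empty("no convergence"))
  if (s < 0.5) return(empty("sigma below 0.5 px"))
  if (p[["x0"]] < min(cols) || p[["x0"]] > max(cols) ||
      p[["y0"]] < min(rows) || p[["y0"]] > max(rows))
    return(empty("centre left fit window"))
  if (p[["A"]] <= 0) return(empty("non-positive amplitude"))
  rms <- sqrt(mean(res_fun(p)^2))
  tibble(x_px = p[["x0"]], y_px = p[["y0"]], sigma_px = s,
         amplitude = p[["A"]], offset = p[["I0"]],
         fit_residual = rms / p[["A"]], converged = TRUE)
}

#' Detect and measure granules in every frame of a stack
#'
#' Runs [detect_candidates()] and [fit_spot_gaussian()] on each frame and
#' converts the fits to physical units. Candidate maxima whose fits
#' collapse onto the same sub-pixel centre (noise can split one granule
#' into several local maxima) are de-duplicated, keeping the
#' lowest-residual fit.
#'
#' Units and conventions: positions in µm (pixel centres at
#' integer coordinates, top-left pixel centre at the origin, x rightward,
#' y downward), diameter = Gaussian FWHM in µm, intensity = integrated
#' Gaussian area. By default spots are restricted to the 0.5-1.5 µm
#' diameter class via [filter_by_diameter()].
#'
#' @param stack An [image_stack()].
#' @param min_contrast,min_separation_px,smooth_sigma Passed to
#'   [detect_candidates()].
#' @param fit_window_px Fit window side; default `NULL` chooses
#'   2 x the FWHM of `expected_diameter_um` (odd, at least 15 px), wide
#'   enough to cover +/- 2.4 sigma of a spot while keeping neighbouring
#'   granules out of the window.
#' @param expected_diameter_um Typical granule diameter used to size the
#'   default window. Default 1.
#' @param diameter_range_um Inclusive diameter bounds in µm, or `NULL` to
#'   keep all sizes. Default `c(0.5, 1.5)`.
#' @param frames Optional integer subset of frames to process.
#' @return Spot tibble: `frame`, `x_um`, `y_um`, `x_px`, `y_px`,
#'   `diameter_um`, `intensity`, `fit_residual`.
#' @export
detect_spots <- function(stack, min_contrast = 4, min_separation_px = 3,
                         smooth_sigma = 1, fit_window_px = NULL,
                         expected_diameter_um = 1,
                         diameter_range_um = c(0.5, 1.5), frames = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixel_size_um
  if (is.null(fit_window_px)) {
    fwhm_px <- expected_diameter_um / px
    fit_window_px <- max(15L, 2L * ceiling(fwhm_px) + 1L)
  }
  frames <- frames %||% seq_along(stack$frames)
  out <- map(frames, function(f) {
    fr <- stack$frames[[f]]
    cand <- detect_candidates(fr, min_contrast, min_separation_px, smooth_sigma)
    if (!nrow(cand)) return(NULL)
    fits <- map2(cand$row, cand$col,
                 function(r, c) fit_spot_gaussian(fr, r, c, fit_window_px))
    fits <- list_rbind(keep(fits, ~ nrow(.x) > 0))
    if (is.null(fits) || !nrow(fits)) return(NULL)
    # several noise-split candidate maxima inside one granule converge to
    # the same sub-pixel centre: keep only the best-residual fit per site
    fits <- arrange(fits, .data$fit_residual)
    keep_fit <- rep(TRUE, nrow(fits))
    for (i in seq_len(nrow(fits))[-1]) {
      prev <- which(keep_fit[seq_len(i - 1)])
      d2 <- (fits$x_px[prev] - fits$x_px[i])^2 +
            (fits$y_px[prev] - fits$y_px[i])^2
      if (any(d2 < min_separation_px^2)) keep_fit[i] <- FALSE
    }
    mutate(fits[keep_fit, ], frame = f, .before = 1)
  })
  out <- list_rbind(keep(out, ~ !is.null(.x)))
  if (is.null(out) || !nrow(out)) {
    out <- tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
                  sigma_px = numeric(), amplitude = numeric(),
                  offset = numeric(), fit_residual = numeric(),
                  converged = logical())
  }
  out <- mutate(out,
    x_um = (.data$x_px - 1) * px,
    y_um = (.data$y_px - 1) * px,
    diameter_um = 2 * sqrt(2 * log(2)) * .data$sigma_px * px,
    intensity = 2 * pi * .data$sigma_px^2 * .data$amplitude
  ) |>
    select("frame", "x_um", "y_um", "x_px", "y_px", "diameter_um",
           "intensity", "fit_residual")
  if (!is.null(diameter_range_um))
    out <- filter_by_diameter(out, diameter_range_um[1], diameter_range_um[2])
  attr(out, "pixel_size_um") <- px
  attr(out, "dt_s") <- stack$dt_s
  out
}

#' Keep spots within an optical-diameter class
#'
#' Retains spots whose diameter satisfies `lo <= diameter_um <= hi`
#' (inclusive bounds). The default 0.5-1.5 µm window selects the granule
#' size class used for microrheology.
#'
#' @param spots Tibble with a `diameter_um` column.
#' @param lo,hi Inclusive bounds, µm.
#' @return The filtered tibble, original row order preserved.
#' @export
filter_by_diameter <- function(spots, lo = 0.5, hi = 1.5) {
  stopifnot("diameter_um" %in% names(spots), lo <= hi)
  at <- attributes(spots)
  out <- filter(spots, .data$diameter_um >= lo, .data$diameter_um <= hi)
  attr(out, "pixel_size_um") <- at$pixel_size_um
  attr(out, "dt_s") <- at$dt_s
  out
}
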