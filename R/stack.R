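#' Image stack container
#'
#' A minimal container for a single-channel time-lapse stack: an ordered
#' list of numeric matrices (row = y, increasing downward; column = x,
#' increasing rightward) plus the physical pixel size and the frame
#' interval. Pixel centres sit at integer pixel coordinates; the physical
#' position of pixel (row, col) is `((col - 1) * pixel_size_um,
#' (row - 1) * pixel_size_um)` so the top-left pixel centre is the origin.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param pixel_size_um Pixel size, µm.
#' @param dt_s Frame interval, seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, dt_s) {
  if (!length(frames)) abort("`frames` must contain at least one frame.")
  dims <- unique(map(frames, dim))
  if (length(dims) != 1) abort("All frames must share one dimension.")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    abort("`pixel_size_um` must be positive.")
  if (!is.finite(dt_s) || dt_s <= 0) abort("`dt_s` must be positive.")
  structure(list(frames = frames, pixel_size_um = pixel_size_um, dt_s = dt_s),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g um/px, dt = %.5g s\n",
              length(x$frames), d[1], d[2], x$pixel_size_um, x$dt_s))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read / write multi-page grayscale TIFF stacks
#'
#' `read_stack()` loads a multi-page grayscale TIFF; values are rescaled
#' back to integer counts (the inverse of `write_stack()`'s 16-bit
#' quantisation). Pixel size and frame rate are not stored in plain
#' baseline TIFF, so they must be supplied.
#'
#' @param path File path.
#' @param pixel_size_um Pixel size, µm.
#' @param frame_rate_hz Sampling frequency, Hz.
#' @return `read_stack()` an [image_stack()]; `write_stack()` the path,
#'   invisibly.
#' @export
read_stack <- function(path, pixel_size_um = 0.05, frame_rate_hz = 512) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- map(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 65535)
  })
  image_stack(frames, pixel_size_um, 1 / frame_rate_hz)
}

#' @param stack An [image_stack()].
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- map(stack$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}
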