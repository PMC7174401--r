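#' Remove collective drift from trajectories
#'
#' Two-stage correction of the collective motion of the whole nucleus:
#'
#' 1. **Rigid alignment** (`method = "rigid_com"`, default): for every
#'    consecutive frame pair, the rigid transform (rotation +
#'    translation, no scaling) best aligning the particles present in
#'    both frames is estimated by SVD ([estimate_rigid_transform()]);
#'    the accumulated transform is inverted and applied, mapping all
#'    frames back into the first frame's orientation.
#' 2. **Centre-of-mass subtraction**: the intensity-weighted
#'    centre-of-mass drift path `r0(t)` is recomputed on the
#'    rigid-corrected positions and subtracted: `r'(t) = r(t) - r0(t)`.
#'
#' The drift path is assembled incrementally: for every consecutive
#' frame pair the intensity-weighted mean displacement of the particles
#' present in *both* frames is added to the running path, which is
#' anchored at the first frame's absolute centre of mass. When every
#' particle is present in every frame with constant intensity this
#' equals the per-frame centre of mass exactly; when tracks start or end
#' mid-recording it does **not** inherit the jump that the per-frame
#' centre of mass makes as the tracked set changes -- such jumps would
#' otherwise contaminate every displacement spanning them and inflate
#' the MSD in proportion to the lag.
#'
#' `method = "com"` skips stage 1. Frame pairs with fewer than 2 common
#' particles fall back to the identity transform in stage 1; frame pairs
#' sharing no particle keep the previous drift estimate and are flagged
#' `interpolated` in the drift record.
#'
#' @param traj Trajectory tibble (`particle_id`, `frame`, `x_um`,
#'   `y_um`, `intensity`).
#' @param method `"rigid_com"` or `"com"`.
#' @return `traj` with added `x_corr_um`, `y_corr_um` and attribute
#'   `drift_record`: a tibble per frame with the incremental rigid
#'   transform (`theta_rad`, `tx_um`, `ty_um`), the centre-of-mass
#'   drift path after rigid correction (`com_x_um`, `com_y_um`) and an
#'   `interpolated` flag.
#' @export
drift_correct <- function(traj, method = c("rigid_com", "com")) {
  method <- arg_match(method)
  stopifnot(all(c("particle_id", "frame", "x_um", "y_um", "intensity")
                %in% names(traj)))
  at <- attributes(traj)
  frames <- seq(min(traj$frame), max(traj$frame))
  by_frame <- split(traj, factor(traj$frame, levels = frames))

  n_f <- length(frames)
  inc <- tibble(frame = frames, theta_rad = 0, tx_um = 0, ty_um = 0)
  xr <- traj$x_um
  yr <- traj$y_um

  if (method == "rigid_com" && n_f > 1) {
    # cumulative transform A_k, b_k with r_k = A_k r_1 + b_k
    A <- diag(2); b <- c(0, 0)
    corr <- vector("list", n_f)
    corr[[1]] <- cbind(by_frame[[1]]$x_um, by_frame[[1]]$y_um)
    for (k in 2:n_f) {
      a <- by_frame[[k - 1]]; d <- by_frame[[k]]
      common <- intersect(a$particle_id, d$particle_id)
      if (length(common) >= 2) {
        pa <- as.matrix(a[match(common, a$particle_id), c("x_um", "y_um")])
        pb <- as.matrix(d[match(common, d$particle_id), c("x_um", "y_um")])
        tr <- estimate_rigid_transform(pa, pb)
      } else {
        tr <- list(rotation = diag(2), theta_rad = 0, translation = c(0, 0))
      }
      inc$theta_rad[k] <- tr$theta_rad
      inc$tx_um[k] <- tr$translation[1]
      inc$ty_um[k] <- tr$translation[2]
      A <- tr$rotation %*% A
      b <- as.vector(tr$rotation %*% b) + tr$translation
      # invert: r_1-frame coords = A^-1 (r_k - b)
      pts <- cbind(d$x_um, d$y_um)
      corr[[k]] <- sweep(pts, 2, b) %*% A # (A^-1)^T = A, applied from right
    }
    # map the frame-major corrected matrix back onto the input row order
    mat <- do.call(rbind, corr)
    flat <- list_rbind(map(by_frame, ~ .x["particle_id"]))
    key_all <- paste(traj$frame, traj$particle_id)
    key_flat <- paste(rep(frames, vapply(by_frame, nrow, 1L)),
                      flat$particle_id)
    pos <- match(key_all, key_flat)
    xr <- mat[pos, 1]
    yr <- mat[pos, 2]
  }

  work <- mutate(traj, x_rigid = xr, y_rigid = yr)
  # incremental drift path: intensity-weighted mean displacement of the
  # particles common to each consecutive frame pair, anchored at the
  # first frame's absolute centre of mass (see Details)
  rby <- split(work, factor(work$frame, levels = frames))
  r0 <- matrix(0, n_f, 2)
  interpolated <- logical(n_f)
  f1 <- rby[[1]]
  if (nrow(f1)) {
    r0[1, ] <- c(sum(f1$x_rigid * f1$intensity) / sum(f1$intensity),
                 sum(f1$y_rigid * f1$intensity) / sum(f1$intensity))
  } else {
    interpolated[1] <- TRUE
  }
  if (n_f > 1) {
    for (k in 2:n_f) {
      a <- rby[[k - 1]]; d <- rby[[k]]
      common <- intersect(a$particle_id, d$particle_id)
      if (length(common)) {
        ia <- match(common, a$particle_id)
        id <- match(common, d$particle_id)
        w <- (a$intensity[ia] + d$intensity[id]) / 2
        step <- c(sum((d$x_rigid[id] - a$x_rigid[ia]) * w),
                  sum((d$y_rigid[id] - a$y_rigid[ia]) * w)) / sum(w)
      } else {
        step <- c(0, 0)
        interpolated[k] <- TRUE
      }
      r0[k, ] <- r0[k - 1, ] + step
    }
  }
  com <- tibble(frame = frames, com_x_um = r0[, 1], com_y_um = r0[, 2])
  out <- work |>
    left_join(com, by = "frame") |>
    mutate(x_corr_um = .data$x_rigid - .data$com_x_um,
           y_corr_um = .data$y_rigid - .data$com_y_um) |>
    select(-"x_rigid", -"y_rigid", -"com_x_um", -"com_y_um")
  record <- inc |>
    left_join(com, by = "frame") |>
    mutate(interpolated = interpolated)
  attr(out, "drift_record") <- record
  attr(out, "pixel_size_um") <- at$pixel_size_um
  attr(out, "dt_s") <- at$dt_s
  attr(out, "qc_log") <- at$qc_log
  out
}
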