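#' Link detected spots into trajectories
#'
#' Computes SURF-style descriptors for the spots of every frame, matches
#' consecutive frames with [match_frames()] (mutual nearest neighbour in
#' descriptor space, gated by a spatial displacement limit, with a
#' nearest-neighbour fallback for border spots) and chains the links into
#' trajectories. A spot without a link terminates its trajectory; a spot
#' without a predecessor starts a new one (no gap closing).
#'
#' @param stack An [image_stack()].
#' @param spots Optional spot tibble from [detect_spots()]; detected with
#'   defaults when omitted.
#' @param max_disp_um Spatial gate for frame-to-frame links; default
#'   5 x the RMS step `sqrt(4 * expected_D_um2_s * dt)`.
#' @param expected_D_um2_s Diffusivity scale used for the default gate.
#'   Default 0.5 µm²/s.
#' @param use_descriptors Use descriptor matching (`TRUE`, default) or
#'   pure gated nearest-neighbour linking.
#' @param nucleus_id Identifier for the output `nucleus_id` column.
#' @param ... Passed to [detect_spots()] when `spots` is omitted.
#' @return Trajectory tibble: `nucleus_id`, `particle_id`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `diameter_um`, `intensity`, `fit_residual`,
#'   `link_method`. Attributes `pixel_size_um`, `dt_s`.
#' @export
track_spots <- function(stack, spots = NULL, max_disp_um = NULL,
                        expected_D_um2_s = 0.5, use_descriptors = TRUE,
                        nucleus_id = "nucleus1", ...) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(spots)) spots <- detect_spots(stack, ...)
  if (!nrow(spots)) abort("No spots to link.")
  dt <- stack$dt_s
  max_disp_um <- max_disp_um %||% (5 * sqrt(4 * expected_D_um2_s * dt))

  frames_present <- sort(unique(spots$frame))
  by_frame <- split(spots, spots$frame)
  desc <- lapply(by_frame, function(s) {
    if (use_descriptors)
      compute_descriptors(stack$frames[[s$frame[1]]], s)
    else {
      s$descriptor <- vector("list", nrow(s))
      s
    }
  })

  track_of <- vector("list", length(frames_present)) # spot row -> track id
  next_id <- 1L
  new_track <- function(n) {
    ids <- next_id:(next_id + n - 1L)
    next_id <<- next_id + n
    ids
  }
  track_of[[1]] <- new_track(nrow(by_frame[[1]]))
  for (k in seq_along(frames_present)[-1]) {
    a <- desc[[k - 1]]; b <- desc[[k]]
    consecutive <- frames_present[k] == frames_present[k - 1] + 1L
    ids <- rep(NA_integer_, nrow(b))
    meth <- rep(NA_character_, nrow(b))
    if (consecutive) {
      m <- match_frames(a, b, max_disp_um)
      ids[m$j] <- track_of[[k - 1]][m$i]
      meth[m$j] <- m$method
    }
    fresh <- is.na(ids)
    if (any(fresh)) ids[fresh] <- new_track(sum(fresh))
    track_of[[k]] <- ids
    by_frame[[k]]$link_method <- meth
  }
  by_frame[[1]]$link_method <- NA_character_

  out <- list_rbind(imap(by_frame, function(s, nm) {
    k <- match(as.integer(nm), frames_present)
    mutate(s, particle_id = sprintf("t%04d", track_of[[k]]))
  }))
  out <- out |>
    mutate(nucleus_id = nucleus_id,
           t_s = (.data$frame - 1) * dt) |>
    select("nucleus_id", "particle_id", "frame", "t_s", "x_um", "y_um",
           "diameter_um", "intensity", "fit_residual", "link_method") |>
    arrange(.data$particle_id, .data$frame)
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  attr(out, "dt_s") <- dt
  out
}

#' Quality-control filtering of trajectories
#'
#' Applies the spot-stability discard rules: a trajectory is cut at the
#' first frame where (any enabled rule)
#'
#' * the step length changes by more than `max_step_change` (default
#'   50\%) of the previous step length — either as
#'   `||dr(t)| - |dr(t-1)|| > 0.5 |dr(t-1)|` (`step_mode = "change"`,
#'   default) or as `|dr(t)| > 1.5 |dr(t-1)|` (`step_mode = "ratio"`);
#' * the diameter changes by more than `max_size_change` (default 10\%)
#'   relative to the previous frame;
#' * the intensity changes by more than `max_size_change` relative to the
#'   previous frame.
#'
#' The head before the first violation is kept and accepted if it has at
#' least `min_length` frames; otherwise the trajectory is discarded with
#' the triggering rule as reason. Filtering is per-trajectory and
#' deterministic.
#'
#' @param traj Trajectory tibble (needs `particle_id`, `frame`, `x_um`,
#'   `y_um`, `diameter_um`, `intensity`).
#' @param rules Character subset of
#'   `c("displacement", "diameter", "intensity")`; all three by default.
#' @param step_mode `"change"` or `"ratio"` reading of the displacement
#'   rule.
#' @param max_step_change,max_size_change Rule thresholds (fractions).
#' @param min_length Minimum accepted trajectory length, frames.
#'   Default 64.
#' @return The kept rows with a `qc_status` column (`"accepted"`), plus
#'   attribute `qc_log`: a tibble with one row per input trajectory
#'   (`particle_id`, `n_in`, `n_out`, `status`, `reason`).
#' @export
qc_filter <- function(traj,
                      rules = c("displacement", "diameter", "intensity"),
                      step_mode = c("change", "ratio"),
                      max_step_change = 0.5, max_size_change = 0.1,
                      min_length = 64) {
  step_mode <- arg_match(step_mode)
  rules <- match.arg(rules, c("displacement", "diameter", "intensity"),
                     several.ok = TRUE)
  at <- attributes(traj)

  one <- function(d) {
    d <- arrange(d, .data$frame)
    n <- nrow(d)
    viol <- rep(FALSE, n); why <- rep(NA_character_, n)
    mark <- function(idx, reason) {
      fresh <- idx[!viol[idx]]
      viol[idx] <<- TRUE
      why[fresh] <<- ifelse(is.na(why[fresh]), reason, why[fresh])
    }
    if (n >= 2 && "diameter" %in% rules) {
      rel <- abs(diff(d$diameter_um)) / head(d$diameter_um, -1)
      mark(which(rel > max_size_change) + 1L, "diameter_jump")
    }
    if (n >= 2 && "intensity" %in% rules) {
      rel <- abs(diff(d$intensity)) / head(d$intensity, -1)
      mark(which(rel > max_size_change) + 1L, "intensity_jump")
    }
    if (n >= 3 && "displacement" %in% rules) {
      step <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2) # length n-1
      prev <- head(step, -1); cur <- tail(step, -1)
      bad <- if (step_mode == "change")
        abs(cur - prev) > max_step_change * prev
      else
        cur > (1 + max_step_change) * prev
      mark(which(bad) + 2L, "step_jump")
    }
    first <- if (any(viol)) which(viol)[1] else n + 1L
    kept <- d[seq_len(first - 1L), ]
    status <- if (nrow(kept) >= min_length) "accepted" else "discarded"
    reason <- if (first <= n) why[first]
      else if (status == "discarded") "too_short" else NA_character_
    if (status == "discarded" && is.na(reason)) reason <- "too_short"
    log <- tibble(particle_id = d$particle_id[1], n_in = n,
                  n_out = if (status == "accepted") nrow(kept) else 0L,
                  status = status, reason = reason)
    list(kept = if (status == "accepted")
           mutate(kept, qc_status = "accepted") else NULL,
         log = log)
  }

  pieces <- map(split(traj, traj$particle_id), one)
  kept <- list_rbind(keep(map(pieces, "kept"), ~ !is.null(.x)))
  if (is.null(kept) || !nrow(kept)) {
    kept <- traj[0, ]
    kept$qc_status <- character()
  }
  kept <- arrange(kept, .data$particle_id, .data$frame)
  attr(kept, "qc_log") <- list_rbind(map(pieces, "log"))
  attr(kept, "pixel_size_um") <- at$pixel_size_um
  attr(kept, "dt_s") <- at$dt_s
  kept
}

#' Intensity-weighted centre of mass per frame
#'
#' `r0(t) = sum_i r_i(t) I_i(t) / sum_i I_i(t)`, the collective frame of
#' reference used for drift correction.
#'
#' @param spots Tibble with `frame`, `x_um`, `y_um`, `intensity`.
#' @return Tibble `frame`, `com_x_um`, `com_y_um`, `n_spots`.
#' @export
center_of_mass <- function(spots) {
  stopifnot(all(c("frame", "x_um", "y_um", "intensity") %in% names(spots)))
  if (!nrow(spots)) abort("At least one spot is required.")
  out <- spots |>
    group_by(.data$frame) |>
    summarise(total_I = sum(.data$intensity),
              com_x_um = sum(.data$x_um * .data$intensity) / .data$total_I,
              com_y_um = sum(.data$y_um * .data$intensity) / .data$total_I,
              n_spots = dplyr::n(), .groups = "drop")
  if (any(out$total_I <= 0))
    abort("Zero total intensity in at least one frame.")
  select(out, "frame", "com_x_um", "com_y_um", "n_spots")
}

#' Least-squares rigid alignment of two point sets (Kabsch)
#'
#' Finds the rotation `R` (det +1, no scaling or reflection) and
#' translation `t` minimising `sum ||R p_i + t - q_i||^2` via the SVD of
#' the cross-covariance of the centred point sets; the reflection branch
#' is corrected by the sign of the determinant.
#'
#' @param p,q Numeric matrices (n x 2) of corresponding points.
#' @return List with `rotation` (2 x 2), `theta_rad`, `translation`
#'   (length 2), `rms_residual`. With fewer than 2 pairs the identity is
#'   returned with a warning.
#' @export
estimate_rigid_transform <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 2, ncol(q) == 2, nrow(p) == nrow(q))
  if (nrow(p) < 2) {
    warn("Fewer than 2 point pairs; returning identity transform.")
    return(list(rotation = diag(2), theta_rad = 0,
                translation = c(0, 0), rms_residual = NA_real_))
  }
  pc <- colMeans(p); qc <- colMeans(q)
  H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  t <- qc - as.vector(R %*% pc)
  fitted <- sweep(p %*% t(R), 2, t, "+")
  list(rotation = R,
       theta_rad = atan2(R[2, 1], R[1, 1]),
       translation = t,
       rms_residual = sqrt(mean(rowSums((fitted - q)^2))))
}
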