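# Scale- and rotation-invariant spot descriptors built on integral
# images and Haar-wavelet responses (SURF construction): box-filter
# determinant-of-Hessian scale selection at each anchor, dominant
# orientation from Haar responses in a circular neighbourhood, and a
# 64-dimensional descriptor of summed oriented wavelet responses over a
# 4 x 4 subregion grid, unit-normalised so it is invariant to uniform
# intensity rescaling.

# integral image padded with a leading zero row/column, so the sum over
# rows r0..r1, cols c0..c1 is ii[r1+1,c1+1]-ii[r0,c1+1]-ii[r1+1,c0]+ii[r0,c0]
integral_image <- function(m) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum) # transposed double cumsum
  ii <- t(ii)
  rbind(0, cbind(0, ii))
}

# vectorised box sum; r0/r1/c0/c1 are equal-length integer vectors,
# assumed inside the image
box_sum <- function(ii, r0, r1, c0, c1) {
  nr <- nrow(ii)
  idx <- function(r, c) (c - 1L) * nr + r
  ii[idx(r1 + 1L, c1 + 1L)] - ii[idx(r0, c1 + 1L)] -
    ii[idx(r1 + 1L, c0)] + ii[idx(r0, c0)]
}

# Haar wavelet responses of half-size hs at points (r, c); returns a list
# with dx (bright-to-the-right positive) and dy (bright-below positive)
haar_xy <- function(ii, r, c, hs) {
  dx <- box_sum(ii, r - hs, r + hs, c + 1L, c + hs) -
        box_sum(ii, r - hs, r + hs, c - hs, c - 1L)
  dy <- box_sum(ii, r + 1L, r + hs, c - hs, c + hs) -
        box_sum(ii, r - hs, r - 1L, c - hs, c + hs)
  list(dx = dx, dy = dy)
}

# box-filter approximations of the scaled Hessian at one pixel for
# filter size L (odd multiple of 3); lobe l = L/3
det_hessian_at <- function(ii, r, c, L) {
  l <- L %/% 3L
  h <- (L - 1L) %/% 2L
  nr <- nrow(ii) - 1L; nc <- ncol(ii) - 1L
  if (r - h < 1L || r + h > nr || c - h < 1L || c + h > nc) return(NA_real_)
  wl <- (l - 1L) %/% 2L # half-width of the narrow lobe
  # Dyy: three stacked boxes (width 2l-1, height l), weights 1,-2,1
  cw0 <- c - (l - 1L); cw1 <- c + (l - 1L)
  dyy <- box_sum(ii, r - h, r - h + l - 1L, cw0, cw1) -
    2 * box_sum(ii, r - wl, r + wl, cw0, cw1) +
    box_sum(ii, r + h - l + 1L, r + h, cw0, cw1)
  # Dxx by symmetry: three side-by-side boxes (height 2l-1, width l)
  rw0 <- r - (l - 1L); rw1 <- r + (l - 1L)
  dxx <- box_sum(ii, rw0, rw1, c - h, c - h + l - 1L) -
    2 * box_sum(ii, rw0, rw1, c - wl, c + wl) +
    box_sum(ii, rw0, rw1, c + h - l + 1L, c + h)
  # Dxy: four l x l boxes on the diagonals
  dxy <- box_sum(ii, r - l, r - 1L, c + 1L, c + l) +
    box_sum(ii, r + 1L, r + l, c - l, c - 1L) -
    box_sum(ii, r - l, r - 1L, c - l, c - 1L) -
    box_sum(ii, r + 1L, r + l, c + 1L, c + l)
  dxx <- dxx / L^2; dyy <- dyy / L^2; dxy <- dxy / L^2
  dxx * dyy - (0.9 * dxy)^2
}

# SURF scale at an anchor: argmax of |det Hessian| over a filter-size
# ladder; scale s = 1.2 * L / 9
surf_scale <- function(ii, r, c, sizes = c(9L, 15L, 21L, 27L, 39L, 51L, 75L)) {
  doh <- vapply(sizes, function(L) det_hessian_at(ii, r, c, L), numeric(1))
  if (all(is.na(doh))) return(NA_real_)
  1.2 * sizes[which.max(abs(doh))] / 9
}

# dominant orientation from Haar responses (wavelet size 4s) at grid
# points within radius 6s, Gaussian-weighted (sd 2.5s), summed over a
# sliding pi/3 window
surf_orientation <- function(ii, r, c, s) {
  pts <- expand.grid(i = -6:6, j = -6:6)
  pts <- pts[pts$i^2 + pts$j^2 <= 36, ]
  pr <- as.integer(round(r + pts$j * s))
  pc <- as.integer(round(c + pts$i * s))
  hs <- max(1L, as.integer(round(2 * s)))
  nr <- nrow(ii) - 1L; nc <- ncol(ii) - 1L
  ok <- pr - hs >= 1L & pr + hs <= nr & pc - hs >= 1L & pc + hs <= nc
  if (sum(ok) < 8) return(NA_real_)
  h <- haar_xy(ii, pr[ok], pc[ok], hs)
  w <- exp(-(pts$i[ok]^2 + pts$j[ok]^2) / (2 * 2.5^2))
  dx <- h$dx * w; dy <- h$dy * w
  ang <- atan2(dy, dx)
  cand <- seq(-pi, pi, length.out = 41)[-41]
  best <- c(0, -Inf)
  for (th in cand) {
    d <- (ang - th + pi) %% (2 * pi) - pi
    sel <- abs(d) <= pi / 6
    if (!any(sel)) next
    sx <- sum(dx[sel]); sy <- sum(dy[sel])
    n2 <- sx^2 + sy^2
    if (n2 > best[2]) best <- c(atan2(sy, sx), n2)
  }
  best[1]
}

# 64-d descriptor: 4x4 subregions of a 20s window oriented along theta,
# 5x5 samples per subregion, Haar size 2s, responses rotated into the
# descriptor frame, Gaussian-weighted (sd 3.3s), per-subregion
# (sum dxi, sum |dxi|, sum deta, sum |deta|), unit-normalised
surf_descriptor <- function(ii, r, c, s, theta) {
  u <- seq(-9.5, 9.5, by = 1) # sample offsets in units of s
  grid <- expand.grid(u = u, v = u)
  ct <- cos(theta); st <- sin(theta)
  gx <- c + s * (ct * grid$u - st * grid$v)
  gy <- r + s * (st * grid$u + ct * grid$v)
  pr <- as.integer(round(gy)); pc <- as.integer(round(gx))
  hs <- max(1L, as.integer(round(s)))
  nr <- nrow(ii) - 1L; nc <- ncol(ii) - 1L
  if (any(pr - hs < 1L) || any(pr + hs > nr) ||
      any(pc - hs < 1L) || any(pc + hs > nc))
    return(NULL)
  h <- haar_xy(ii, pr, pc, hs)
  w <- exp(-(grid$u^2 + grid$v^2) / (2 * 3.3^2))
  dx <- h$dx * w; dy <- h$dy * w
  dxi <-  ct * dx + st * dy
  deta <- -st * dx + ct * dy
  sub <- interaction(ceiling((grid$u + 10) / 5), ceiling((grid$v + 10) / 5))
  f <- function(v, g) as.vector(tapply(v, g, sum))
  desc <- as.vector(rbind(f(dxi, sub), f(abs(dxi), sub),
                          f(deta, sub), f(abs(deta), sub)))
  n <- sqrt(sum(desc^2))
  if (n == 0) return(NULL)
  desc / n
}

#' Compute SURF-style descriptors for detected spots
#'
#' For each spot anchor: a box-filter determinant-of-Hessian scale
#' estimate on the frame's integral image, a dominant orientation from
#' Haar-wavelet responses in a circular neighbourhood, and a
#' unit-normalised 64-dimensional descriptor of summed oriented wavelet
#' responses over a 4 x 4 grid. Spots too close to the border for the
#' descriptor window keep `descriptor = NULL` and remain trackable
#' through the nearest-neighbour fallback of [match_frames()].
#'
#' @param frame Numeric matrix the spots were detected in.
#' @param spots Spot tibble with `x_px`, `y_px` columns (see
#'   [detect_spots()]).
#' @return `spots` with added columns `scale_px`, `orientation_rad`, and
#'   a list-column `descriptor` (numeric(64) or `NULL`).
#' @export
compute_descriptors <- function(frame, spots) {
  stopifnot(is.matrix(frame), all(c("x_px", "y_px") %in% names(spots)))
  ii <- integral_image(frame)
  n <- nrow(spots)
  scale <- numeric(n); orient <- numeric(n); desc <- vector("list", n)
  for (k in seq_len(n)) {
    r <- as.integer(round(spots$y_px[k]))
    c <- as.integer(round(spots$x_px[k]))
    s <- surf_scale(ii, r, c)
    if (is.na(s)) { scale[k] <- NA; orient[k] <- NA; next }
    th <- surf_orientation(ii, r, c, s)
    scale[k] <- s; orient[k] <- th
    if (!is.na(th)) {
      dk <- surf_descriptor(ii, r, c, s, th)
      if (!is.null(dk)) desc[[k]] <- dk # NULL assignment would drop the slot
    }
  }
  out <- mutate(spots, scale_px = scale, orientation_rad = orient)
  out$descriptor <- desc
  out
}

#' Match spots between two consecutive frames
#'
#' Mutual nearest neighbours in descriptor space, gated by spatial
#' distance: a pair (i, j) is linked when each is the other's closest
#' descriptor among spots within `max_disp_um`. Spots without a
#' descriptor (border cases) are matched by mutual spatial nearest
#' neighbour under the same gate. Matching is one-to-one and symmetric;
#' unmatched spots start or terminate trajectories upstream.
#'
#' @param spots_a,spots_b Descriptor tibbles from [compute_descriptors()]
#'   for frames t and t+1 (need `x_um`, `y_um`, `descriptor`).
#' @param max_disp_um Spatial gate, µm.
#' @return Tibble `i` (row in `spots_a`), `j` (row in `spots_b`),
#'   `desc_dist` (NA for fallback links), `disp_um`, `method`
#'   (`"descriptor"` or `"nearest"`).
#' @export
match_frames <- function(spots_a, spots_b, max_disp_um) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  none <- tibble(i = integer(), j = integer(), desc_dist = numeric(),
                 disp_um = numeric(), method = character())
  if (na == 0 || nb == 0) return(none)

  sp <- outer(spots_a$x_um, spots_b$x_um, "-")^2 +
        outer(spots_a$y_um, spots_b$y_um, "-")^2
  gate <- sp <= max_disp_um^2

  has_a <- !vapply(spots_a$descriptor, is.null, logical(1))
  has_b <- !vapply(spots_b$descriptor, is.null, logical(1))
  dd <- matrix(Inf, na, nb)
  if (any(has_a) && any(has_b)) {
    A <- do.call(rbind, spots_a$descriptor[has_a])
    B <- do.call(rbind, spots_b$descriptor[has_b])
    d2 <- pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0)
    dd[has_a, has_b] <- sqrt(d2)
  }
  dd[!gate] <- Inf

  links <- mutual_nn(dd)
  matched_a <- links$i; matched_b <- links$j
  out <- if (nrow(links)) {
    mutate(links, desc_dist = dd[cbind(links$i, links$j)],
           method = "descriptor")
  } else {
    none[, c("i", "j", "desc_dist", "method")]
  }

  # fallback: spatial mutual NN among still-unmatched spots
  sp2 <- sqrt(sp)
  sp2[!gate] <- Inf
  sp2[matched_a, ] <- Inf
  sp2[, matched_b] <- Inf
  fb <- mutual_nn(sp2)
  if (nrow(fb))
    out <- bind_rows(out, mutate(fb, desc_dist = NA_real_, method = "nearest"))
  if (!nrow(out)) return(none)
  mutate(out, disp_um = sqrt(sp[cbind(.data$i, .data$j)])) |>
    select("i", "j", "desc_dist", "disp_um", "method") |>
    arrange(.data$i)
}

# mutual nearest neighbours of a finite-entry cost matrix
mutual_nn <- function(cost) {
  if (!any(is.finite(cost))) return(tibble(i = integer(), j = integer()))
  jbest <- apply(cost, 1, which.min)
  ibest <- apply(cost, 2, which.min)
  i <- seq_len(nrow(cost))
  ok <- is.finite(cost[cbind(i, jbest)]) & ibest[jbest] == i
  tibble(i = i[ok], j = as.integer(jbest[ok]))
}
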