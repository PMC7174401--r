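test_that("tracking recovers one full trajectory per simulated granule", {
  fx <- cached_fixture("free_jurkat_like")
  traj <- track_spots(fx$stack, nucleus_id = "nuc_a")
  n_frames <- fx$config$n_frames
  n_true <- dplyr::n_distinct(fx$truth$particle_id)
  lens <- dplyr::count(traj, particle_id)
  expect_equal(nrow(lens), n_true)
  expect_true(all(lens$n == n_frames))
  expect_equal(unique(traj$nucleus_id), "nuc_a")
  # each track stays on a single truth particle
  truth <- fx$truth
  near <- function(f, x, y) {
    tr <- truth[truth$frame == f, ]
    tr$particle_id[which.min((tr$x_um - x)^2 + (tr$y_um - y)^2)]
  }
  traj$true_id <- mapply(near, traj$frame, traj$x_um, traj$y_um)
  purity <- tapply(traj$true_id, traj$particle_id,
                   function(z) length(unique(z)))
  expect_true(all(purity == 1))
})

test_that("qc displacement rule reproduces the worked step example", {
  # steps 1.0 then 1.6: |1.6 - 1.0| = 0.6 > 0.5 * 1.0 -> cut at frame 3
  tr <- tibble::tibble(particle_id = "a", frame = 1:4,
                       x_um = c(0, 1, 2.6, 3.0), y_um = 0,
                       diameter_um = 1, intensity = 100)
  out <- qc_filter(tr, min_length = 2)
  expect_equal(out$frame, 1:2)
  log <- attr(out, "qc_log")
  expect_equal(log$reason, "step_jump")
  # steps 1.0 then 1.4 pass the change reading (0.4 <= 0.5)
  tr2 <- tibble::tibble(particle_id = "a", frame = 1:3,
                        x_um = c(0, 1, 2.4), y_um = 0,
                        diameter_um = 1, intensity = 100)
  expect_equal(nrow(qc_filter(tr2, min_length = 2)), 3)
})

test_that("qc step modes implement both readings of the 50% rule", {
  # steps 1.0 then 0.4: "change" cuts (|0.4-1| = 0.6 > 0.5), "ratio"
  # keeps (0.4 < 1.5)
  tr <- tibble::tibble(particle_id = "a", frame = 1:3,
                       x_um = c(0, 1, 1.4), y_um = 0,
                       diameter_um = 1, intensity = 100)
  expect_equal(nrow(qc_filter(tr, step_mode = "change", min_length = 2)), 2)
  expect_equal(nrow(qc_filter(tr, step_mode = "ratio", min_length = 2)), 3)
})

test_that("qc size and intensity rules follow the 10% worked examples", {
  base <- tibble::tibble(particle_id = "a", frame = 1:2,
                         x_um = c(0, 0.01), y_um = 0)
  # diameter 1.00 -> 1.05 um: 5% <= 10%, kept
  d_ok <- dplyr::mutate(base, diameter_um = c(1, 1.05), intensity = 100)
  expect_equal(nrow(qc_filter(d_ok, min_length = 2)), 2)
  # intensity 100 -> 115: 15% > 10%, discarded
  i_bad <- dplyr::mutate(base, diameter_um = 1, intensity = c(100, 115))
  out <- qc_filter(i_bad, min_length = 2)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "qc_log")$reason, "intensity_jump")
  # diameter 1.00 -> 1.15: discarded with the diameter reason
  d_bad <- dplyr::mutate(base, diameter_um = c(1, 1.15), intensity = 100)
  expect_equal(attr(qc_filter(d_bad, min_length = 2),
                    "qc_log")$reason, "diameter_jump")
})

test_that("qc keeps heads meeting the minimum length and logs reasons", {
  good <- tibble::tibble(particle_id = "long", frame = 1:80,
                         x_um = seq(0, 0.79, by = 0.01), y_um = 0,
                         diameter_um = 1, intensity = 100)
  bad <- dplyr::mutate(good, particle_id = "cut",
                       diameter_um = c(rep(1, 70), rep(1.5, 10)))
  short <- tibble::tibble(particle_id = "short", frame = 1:10,
                          x_um = 0, y_um = 0, diameter_um = 1,
                          intensity = 100)
  out <- qc_filter(dplyr::bind_rows(good, bad, short), min_length = 64)
  log <- attr(out, "qc_log")
  expect_setequal(unique(out$particle_id), c("long", "cut"))
  expect_equal(sum(out$particle_id == "cut"), 70)
  expect_equal(log$status[log$particle_id == "short"], "discarded")
  expect_equal(log$reason[log$particle_id == "short"], "too_short")
})

test_that("qc is order-independent across trajectories", {
  set.seed(9)
  tr <- tibble::tibble(
    particle_id = rep(c("a", "b"), each = 70), frame = rep(1:70, 2),
    x_um = cumsum(rnorm(140, 0, 1e-3)), y_um = 0,
    diameter_um = 1, intensity = 100)
  shuffled <- tr[sample(nrow(tr)), ]
  a <- qc_filter(tr)
  b <- qc_filter(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("centre of mass matches the weighted-mean worked examples", {
  s <- tibble::tibble(frame = 1, x_um = c(0, 2), y_um = 0,
                      intensity = c(1, 3))
  com <- center_of_mass(s)
  expect_equal(com$com_x_um, 1.5)
  expect_equal(com$com_y_um, 0)
  one <- tibble::tibble(frame = 1, x_um = 4.2, y_um = -1, intensity = 7)
  expect_equal(center_of_mass(one)$com_x_um, 4.2)
  eq <- tibble::tibble(frame = 1, x_um = c(0, 1, 2), y_um = c(0, 3, 0),
                       intensity = 5)
  expect_equal(center_of_mass(eq)$com_x_um, 1)
  expect_equal(center_of_mass(eq)$com_y_um, 1)
  zero <- tibble::tibble(frame = 1, x_um = 0, y_um = 0, intensity = 0)
  expect_error(center_of_mass(zero), "intensity")
})

test_that("rigid alignment reproduces the constructed 90-degree example", {
  p <- rbind(c(0, 0), c(1, 0), c(0, 1))
  q <- rbind(c(2, 3), c(2, 4), c(1, 3))
  tf <- estimate_rigid_transform(p, q)
  expect_equal(tf$theta_rad, pi / 2, tolerance = 1e-12)
  expect_equal(tf$translation, c(2, 3), tolerance = 1e-12)
  expect_lt(tf$rms_residual, 1e-12)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
})

test_that("rigid alignment of identical sets is the identity", {
  set.seed(4)
  p <- matrix(rnorm(20), 10, 2)
  tf <- estimate_rigid_transform(p, p)
  expect_equal(tf$rotation, diag(2), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0), tolerance = 1e-12)
})

test_that("rigid alignment recovers a noisy transform within 0.1 degree", {
  set.seed(5)
  p <- matrix(runif(100, 0, 10), 50, 2)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- sweep(p %*% t(R), 2, c(1, -2), "+") + matrix(rnorm(100, 0, 0.01 * 0.05), 50, 2)
  tf <- estimate_rigid_transform(p, q)
  expect_lt(abs(tf$theta_rad - th), 0.1 * pi / 180)
})

test_that("fewer than two pairs yields an identity with a warning", {
  expect_warning(tf <- estimate_rigid_transform(matrix(1:2, 1), matrix(3:4, 1)),
                 "identity")
  expect_equal(tf$rotation, diag(2))
})
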