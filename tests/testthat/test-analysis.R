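test_that("step angles are displacement bearings over the interval", {
  # hand-built log: one cell moving E, then W, then NE at 45 degrees
  pos <- array(0, dim = c(4, 1, 2))
  pos[, 1, 1] <- c(0, 0.1, 0, 0.05)
  pos[, 1, 2] <- c(0, 0, 0, 0.05)
  log <- structure(list(times = c(0, 1, 2, 3), positions = pos,
                        cell_ids = 1L, record_stride = 1L,
                        sensitivity = "all", taxis_sign = 1),
                   class = "trajectory_log")
  ang <- step_angles(log, 1)
  expect_equal(as.numeric(ang), c(0, pi, pi / 4))
  expect_equal(attr(ang, "n_dropped"), 0L)
  # zero-displacement intervals are dropped and counted: zeroing the t = 1
  # record stalls both the first and the second interval
  pos[2, 1, ] <- 0
  log$positions <- pos
  ang <- step_angles(log, 1)
  expect_equal(attr(ang, "n_dropped"), 2L)
  expect_equal(as.numeric(ang), pi / 4)
  # interval must be commensurate with the recording stride
  log$record_stride <- 2L
  log$times <- c(0, 2, 4, 6)
  expect_error(step_angles(log, 5), "multiple")
})

test_that("rose histogram bins and uniformity behave as expected", {
  # all angles at 5 degrees fall in the first 10-degree bin
  rh <- rose(rep(5 * pi / 180, 100), 36)
  expect_equal(rh$counts[1], 100L)
  expect_equal(sum(rh$counts), rh$n_total)
  # uniform angles: bins nearly equal
  set.seed(10)
  rh <- rose(runif(1e5, 0, 2 * pi), 36)
  expect_lt(max(rh$counts) / min(rh$counts), 1.25)
  # rotation by a whole bin shifts counts by one index
  a <- rvm(2000, 1.1, 3)
  r1 <- rose(a, 36)
  r2 <- rose(a + 2 * pi / 36, 36)
  expect_equal(r2$counts, r1$counts[c(36, 1:35)])
  # empty input
  expect_equal(rose(numeric(0))$n_total, 0L)
})

test_that("circular resultant separates aligned from balanced headings", {
  expect_equal(resultant(rep(1.3, 50))$r, 1)
  expect_equal(resultant(rep(1.3, 50))$mean_angle, 1.3)
  expect_equal(resultant(rep(c(0, pi), 50))$r, 0, tolerance = 1e-12)
  set.seed(11)
  expect_lt(resultant(runif(1e5, 0, 2 * pi))$r, 0.01)
  expect_error(resultant(numeric(0)), "no angles")
})

test_that("classifier recovers the generating integration mode", {
  srcs60 <- list(light_source(0.05, theta_deg = 60),
                 light_source(0.05, theta_deg = -60))
  set.seed(21)
  # switching data: 5% toward each source (kappa = 50), 90% uniform
  a_sw <- r_switch_angles(4e4, c(pi / 3, -pi / 3), c(0.05, 0.05), 50)
  cl <- classify_mode(a_sw, srcs60)
  expect_equal(cl$label, "stochastic_switching")
  expect_gt(cl$delta_loglik, 0)
  # vector data: 5% toward the bisector (the vector-sum bearing)
  a_vec <- r_switch_angles(4e4, 0, 2 * 0.05 * cos(pi / 3), 50)
  cl <- classify_mode(a_vec, srcs60)
  expect_equal(cl$label, "vector_integration")
  expect_lt(cl$delta_loglik, 10)
})

test_that("classifier margin grows with source separation", {
  set.seed(22)
  margins <- vapply(c(30, 60, 90), function(sep) {
    th <- sep * pi / 180
    srcs <- list(light_source(0.05, theta = th),
                 light_source(0.05, theta = -th))
    a <- r_switch_angles(4e4, c(th, -th), c(0.05, 0.05), 50)
    classify_mode(a, srcs)$delta_loglik
  }, numeric(1))
  expect_true(all(diff(margins) > 0))
})

test_that("single-source limit: the two mixture models coincide", {
  set.seed(23)
  srcs <- list(light_source(0.05, theta_deg = 45))
  a <- r_switch_angles(2e4, pi / 4, 0.05, 50)
  cl <- classify_mode(a, srcs)
  expect_lt(abs(cl$delta_loglik), 1)
})

test_that("finger metrics recover constructed finger layouts", {
  # three fingers at y = 0, 10, 20, each spanning 3 in y, cell radius 1:
  # widths 3 + 2 = 5, separations 10, ratio 0.5
  pos <- finger_fixture(c(0, 10, 20), extent = 3)
  fm <- finger_metrics(pos, centre = c(0, 0), r_col = 20, bearing = 0,
                       gap_threshold = 2, radius = 1)
  expect_equal(fm$n_fingers, 3L)
  expect_equal(fm$mean_width, 5)
  expect_equal(fm$mean_separation, 10)
  expect_equal(fm$width_sep_ratio, 0.5)
  expect_equal(fm$mean_length, 10)
  # y-extent 8 at spacing 10 gives the ratio ~ 1 regime (the inter-finger
  # gap is exactly 2 here, so a slightly smaller split threshold is used;
  # the split rule is strict)
  pos <- finger_fixture(c(0, 10, 20), extent = 8)
  fm <- finger_metrics(pos, c(0, 0), 20, 0, gap_threshold = 1.9)
  expect_equal(fm$width_sep_ratio, 1)
  # no cells beyond the rim
  fm0 <- finger_metrics(cbind(runif(20, -3, 3), runif(20, -3, 3)),
                        c(0, 0), 20, 0)
  expect_equal(fm0$n_fingers, 0L)
  expect_true(is.na(fm0$width_sep_ratio))
})

test_that("finger metrics are rotation-equivariant", {
  pos <- finger_fixture(c(-8, 2, 13), extent = 4)
  fm0 <- finger_metrics(pos, c(0, 0), 20, 0)
  phi <- 2.1
  rot <- cbind(pos[, 1] * cos(phi) - pos[, 2] * sin(phi),
               pos[, 1] * sin(phi) + pos[, 2] * cos(phi))
  fm1 <- finger_metrics(rot, c(0, 0), 20, phi)
  expect_equal(fm1$n_fingers, fm0$n_fingers)
  expect_equal(fm1$mean_width, fm0$mean_width)
  expect_equal(fm1$mean_separation, fm0$mean_separation)
  expect_equal(fm1$width_sep_ratio, fm0$width_sep_ratio)
  expect_equal((fm1$orientation - phi) %% (2 * pi), fm0$orientation,
               tolerance = 1e-8)
})

test_that("front speed fits the post-egress extent growth", {
  # synthetic log: extent grows at exactly 0.05 R/step from t = 0
  times <- seq(0, 2000, by = 100)
  pos <- array(0, dim = c(length(times), 1, 2))
  pos[, 1, 1] <- 10 + 0.05 * times
  log <- structure(list(times = times, positions = pos, cell_ids = 1L,
                        record_stride = 100L, sensitivity = "all",
                        taxis_sign = 1), class = "trajectory_log")
  fs <- front_speed(log, bearing = 0, r_col = 12)
  expect_equal(fs$speed, 0.05)
  expect_equal(fs$rms, 0, tolerance = 1e-12)
  # a front that never leaves the rim yields the sentinel
  fs0 <- front_speed(log, bearing = 0, r_col = 1e6)
  expect_true(is.na(fs0$speed))
})

test_that("front speed is non-decreasing in the phototaxis probability", {
  speeds <- vapply(c(0.01, 0.05), function(pp) {
    mean(vapply(1:2, function(s) {
      run <- small_run(n_cells = 120, n_steps = 4000, p = pp,
                       seed = 100 + s, record_stride = 100)
      front_speed(run$log, 0, run$state$r_col, min_records = 5)$speed
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(!any(is.na(speeds)))
  expect_lte(speeds[1], speeds[2])
})

test_that("real-units calibration reproduces the one-second time step", {
  expect_equal(calibrate_dt(0.1, 1, 0.1), 1)
  expect_equal(calibrate_dt(0.1, 2, 0.1), 2)
  expect_equal(steps_to_hours(1e5, 1), 27.7778, tolerance = 1e-4)
  expect_error(calibrate_dt(0.1, 1, 0), "positive")
})
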