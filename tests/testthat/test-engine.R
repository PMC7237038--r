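test_that("colony initialisation matches the density convention", {
  p <- taxis_params()
  cfg <- colony_config(
    composition = data.frame(sensitivity = c("red", "green"),
                             fraction = c(0.9, 0.1), taxis_sign = 1),
    sources = list(light_source(0.05, theta_deg = 0, wavelength = "red"),
                   light_source(0.05, theta_deg = 90,
                                wavelength = "green")))
  st <- init_colony(cfg, p, seed = 3)
  expect_equal(st$r_col, sqrt(500 / 0.1))          # 70.71 R
  expect_equal(sum(st$sensitivity == "red"), 450L)  # 90:10 of 500
  expect_equal(sum(st$sensitivity == "green"), 50L)
  d <- sqrt(rowSums(sweep(st$positions, 2, cfg$centre)^2))
  expect_true(all(d <= st$r_col))
  # slime under every cell starts at s0; outside the disc at 0
  rc <- nearest_grid_point(st$positions, st$slime)
  expect_true(all(st$slime$values[rc] == p$s0))
  expect_equal(st$slime$values[1, 1], 0)
  # a colony bigger than its lattice is rejected
  expect_error(init_colony(colony_config(grid_dim = c(60L, 60L),
                                         sources = cfg$sources), p),
               "does not fit")
})

test_that("runs are a pure function of configuration and seed", {
  r1 <- small_run(seed = 42)
  r2 <- small_run(seed = 42)
  expect_identical(r1$log$positions, r2$log$positions)
  expect_identical(r1$state$slime$values, r2$state$slime$values)
  r3 <- small_run(seed = 43)
  expect_false(identical(r1$log$positions, r3$log$positions))
  # cell count conserved, times include endpoints
  expect_equal(dim(r1$log$positions)[2], 40L)
  expect_equal(r1$log$times[1], 0)
  expect_equal(r1$log$times[length(r1$log$times)], 200)
  r0 <- small_run(n_steps = 0)
  expect_equal(r0$log$times, 0)
})

test_that("compiled run loop is bit-identical to the R reference step", {
  p <- taxis_params(n_cells = 25, n_steps = 30)
  for (mode in c("stochastic_switching", "vector_integration")) {
    cfg <- colony_config(
      composition = data.frame(sensitivity = c("all", "all"),
                               fraction = c(0.8, 0.2),
                               taxis_sign = c(1, -1)),
      sources = list(light_source(0.04, theta_deg = 60),
                     light_source(0.03, theta_deg = -45)),
      mode = mode)
    set.seed(123)
    st <- init_colony(cfg, p)
    for (i in 1:30) st <- step_state(st)
    run <- run_colony(cfg, p, seed = 123, record_stride = 30)
    expect_identical(run$state$positions, st$positions)
    expect_identical(run$state$slime$values, st$slime$values)
  }
})

test_that("isolated cell on saturated slime moves f0/gamma0 = 0.1 R", {
  cfg <- colony_config(sources = list(light_source(1, theta_deg = 0)),
                       mode = "single")
  run <- run_colony(cfg, taxis_params(n_cells = 1, n_steps = 1, p_photo = 1),
                    seed = 1, record_stride = 1)
  disp <- run$log$positions[2, 1, ] - run$log$positions[1, 1, ]
  expect_equal(disp, c(0.1, 0), tolerance = 1e-15)
})

test_that("a cell on bare substrate stays put but deposits slime", {
  p <- taxis_params(n_cells = 1, n_steps = 1, p_photo = 1)
  cfg <- colony_config(sources = list(light_source(1, theta_deg = 0)),
                       mode = "single")
  set.seed(1)
  st <- init_colony(cfg, p)
  st$positions[1, ] <- c(100, 100)   # off the colony slime
  rc <- nearest_grid_point(st$positions, st$slime)
  expect_equal(st$slime$values[rc], 0)
  st2 <- step_state(st)
  expect_identical(st2$positions, st$positions)
  expect_equal(st2$slime$values[rc], p$s_rate)
})

test_that("two cells at contact with no propulsion are stationary", {
  p <- taxis_params(n_cells = 2, f0 = 0, n_steps = 5)
  cfg <- colony_config(sources = list(), mode = "single")
  set.seed(2)
  st <- init_colony(cfg, p)
  st$positions <- rbind(c(-1, 0), c(1, 0))
  p0 <- st$positions
  for (i in 1:5) st <- step_state(st)
  expect_equal(st$positions, p0)
})

test_that("the colony boundary traps cells until slime builds up", {
  run <- run_colony(
    colony_config(sources = list(light_source(0.05, theta_deg = 0)),
                  mode = "single"),
    taxis_params(n_cells = 200, n_steps = 1), seed = 6, record_stride = 1)
  r_col <- run$state$r_col
  d1 <- sqrt(rowSums(run$log$positions[2, , ]^2))
  # after one step no cell is more than one maximal step beyond the disc
  expect_true(all(d1 <= r_col + 0.1 + 1e-12))
})

test_that("per-step displacement respects the force and friction bounds", {
  run <- small_run(n_cells = 60, n_steps = 50, record_stride = 1, seed = 9)
  p <- taxis_params(n_cells = 60)
  steps <- run$log$positions[-1, , ] - run$log$positions[-51, , ]
  disp <- sqrt(steps[, , 1]^2 + steps[, , 2]^2)
  # crude global bound: f0 plus the largest possible pili load, at the
  # maximal mobility s_max/(gamma0 s0)
  expect_true(all(disp <= (p$f0 + 59 / p$m) * p$s_max / (p$gamma0 * p$s0)))
})

test_that("parallel update is independent of cell ordering", {
  # with m >= N every in-reach neighbour is attached, so attachment
  # selection consumes no randomness and a pure relabelling of the cells
  # (with relabelled heading draws) must produce the identical step
  p <- taxis_params(n_cells = 12, m = 50L, n_steps = 1)
  cfg <- colony_config(sources = list(light_source(0.05, theta_deg = 0)),
                       mode = "single")
  set.seed(31)
  st <- init_colony(cfg, p)
  draws <- list(u = matrix(runif(24), nrow = 2), att = NULL)
  out1 <- step_state(st, draws = draws)
  perm <- sample(12)
  st2 <- st
  st2$positions <- st$positions[perm, ]
  st2$cell_class <- st$cell_class[perm]
  st2$sensitivity <- st$sensitivity[perm]
  st2$taxis_sign <- st$taxis_sign[perm]
  out2 <- step_state(st2, draws = list(u = draws$u[, perm], att = NULL))
  expect_equal(out2$positions, out1$positions[perm, ], tolerance = 1e-12)
  expect_equal(out2$slime$values, out1$slime$values)
})
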