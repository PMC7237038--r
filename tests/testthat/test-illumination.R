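test_that("source bearings follow the compass convention", {
  expect_equal(source_bearing(c(0, 0), c(1, 0)), 0)          # East
  expect_equal(source_bearing(c(0, 0), c(0, 5)), pi / 2)     # North
  expect_equal(source_bearing(c(0, 0), c(-1, -1)), 5 * pi / 4)
  expect_error(source_bearing(c(2, 3), c(2, 3)), "coincides")
  expect_equal(light_source(0.05, theta_deg = -90)$theta, 3 * pi / 2)
})

test_that("intensity maps to probability by inverse or linear distance law", {
  expect_equal(intensity_to_prob(0.05, d = 1, d_ref = 1), 0.05)
  expect_equal(intensity_to_prob(0.05, d = 2, d_ref = 1), 0.025)
  # linear profile across a 5-colony array: 0.05 down to 0.01
  expect_equal(
    intensity_to_prob(0.05, d = 1:5, d_ref = 1, scheme = "linear",
                      d_far = 5, p_min = 0.01),
    c(0.05, 0.04, 0.03, 0.02, 0.01))
  # clipping
  expect_equal(intensity_to_prob(0.9, d = 0.1, d_ref = 1), 1)
  expect_error(intensity_to_prob(0.05, d = 0), "positive")
})

test_that("vector sum of sources gives resultant probability and bearing", {
  vs <- vector_sum(list(light_source(0.05, theta_deg = 30),
                        light_source(0.05, theta_deg = -30)))
  expect_equal(vs$p_vec, 2 * 0.05 * cos(pi / 6))  # 0.08660254
  expect_equal(vs$theta_vec, 0)
  # exact cancellation: undefined bearing, zero resultant
  vs0 <- vector_sum(list(light_source(0.05, theta_deg = 90),
                         light_source(0.05, theta_deg = -90)))
  expect_equal(vs0$p_vec, 0)
  expect_true(is.na(vs0$theta_vec))
  # single source is its own resultant
  vs1 <- vector_sum(list(light_source(0.05, theta_deg = 0)))
  expect_equal(vs1$p_vec, 0.05)
  expect_equal(vs1$theta_vec, 0)
})

test_that("cells perceive only sources matching their sensitivity", {
  srcs <- list(light_source(0.05, theta_deg = 30, wavelength = "red"),
               light_source(0.05, theta_deg = -30, wavelength = "green"))
  expect_equal(visible_sources("red", srcs), srcs[1])
  expect_equal(visible_sources("all", srcs), srcs)
  expect_length(visible_sources("green", list(srcs[[1]])), 0)
})

test_that("deterministic heading cases behave as specified", {
  # p = 1: always directed
  s <- list(light_source(1, theta_deg = 90))
  h <- draw_headings(50, s, mode = "single", seed = 1)
  expect_true(all(h == pi / 2))
  # negative phototaxis: away from an East source means due West
  h <- draw_headings(50, s_east <- list(light_source(1, theta_deg = 0)),
                     mode = "single", taxis_sign = -1, seed = 1)
  expect_true(all(h == pi))
  # over-unity configurations are rejected
  expect_error(draw_headings(
    10, list(light_source(0.6, theta_deg = 0),
             light_source(0.6, theta_deg = 90)),
    mode = "stochastic_switching"), "sum")
})

test_that("directed-branch frequencies match the source probabilities", {
  n <- 2e4
  srcs <- list(light_source(0.05, theta_deg = 90),
               light_source(0.05, theta_deg = -90))
  d <- draw_headings(n, srcs, mode = "stochastic_switching", seed = 42,
                     detail = TRUE)
  tol <- 4 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(d$branch == 1) - 0.05), tol)
  expect_lt(abs(mean(d$branch == 2) - 0.05), tol)
  expect_lt(abs(mean(d$branch == 0) - 0.90), 4 * sqrt(0.9 * 0.1 / n))
  # directed draws land exactly on the source bearings
  expect_true(all(d$heading[d$branch == 1] == pi / 2))
})

test_that("vector integration with cancelling sources is uniform", {
  srcs <- list(light_source(0.05, theta_deg = 90),
               light_source(0.05, theta_deg = -90))
  h <- draw_headings(2e4, srcs, mode = "vector_integration", seed = 3)
  expect_lt(resultant(h)$r, 0.02)
  # and a cell blind to every source moves purely at random
  h2 <- draw_headings(2e4, srcs, mode = "stochastic_switching",
                      sensitivity = "UV", seed = 3)
  expect_lt(resultant(h2)$r, 0.02)
})

test_that("single-source limit: both integration modes draw identically", {
  s <- list(light_source(0.05, theta_deg = 40))
  h1 <- draw_headings(5000, s, mode = "stochastic_switching", seed = 7)
  h2 <- draw_headings(5000, s, mode = "vector_integration", seed = 7)
  expect_identical(h1, h2)
})

test_that("negative taxis equals positive taxis toward the antipode", {
  s_pos <- list(light_source(0.05, theta_deg = 180))
  s_neg <- list(light_source(0.05, theta_deg = 0))
  h_pos <- draw_headings(5000, s_pos, mode = "single", seed = 11)
  h_neg <- draw_headings(5000, s_neg, mode = "single", taxis_sign = -1,
                         seed = 11)
  expect_identical(h_pos, h_neg)
})

test_that("mirroring source bearings mirrors the heading distribution", {
  n <- 1e5
  up <- draw_headings(n, list(light_source(0.3, theta_deg = 40)),
                      mode = "single", seed = 5)
  dn <- draw_headings(n, list(light_source(0.3, theta_deg = -40)),
                      mode = "single", seed = 6)
  h_up <- rose(up, 36)$counts
  h_dn_mirrored <- rose((2 * pi - dn) %% (2 * pi), 36)$counts
  tv <- sum(abs(h_up - h_dn_mirrored)) / (2 * n)
  expect_lt(tv, 0.02)
})
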