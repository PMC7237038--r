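# brute-force all-pairs neighbour search: the oracle for the binned search
brute_neighbours <- function(positions, ell) {
  n <- nrow(positions)
  lapply(seq_len(n), function(i) {
    d <- sqrt((positions[, 1] - positions[i, 1])^2 +
                (positions[, 2] - positions[i, 2])^2)
    sort(setdiff(which(d <= ell), i))
  })
}

# von Mises sampler (Best & Fisher rejection scheme)
rvm <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# draw angles from the switching mixture: w_k toward each bearing (von Mises,
# concentration kappa), remainder uniform
r_switch_angles <- function(n, bearings, w, kappa) {
  k <- sample(length(bearings) + 1L, n, replace = TRUE,
              prob = c(w, 1 - sum(w)))
  out <- runif(n, 0, 2 * pi)
  for (j in seq_along(bearings)) {
    sel <- k == j
    if (any(sel)) out[sel] <- rvm(sum(sel), bearings[j], kappa)
  }
  out
}

# a small colony under a single East source, for fast engine tests
small_run <- function(n_cells = 40, n_steps = 200, p = 0.05, seed = 1,
                      mode = "single", record_stride = 50, ...) {
  cfg <- colony_config(sources = list(light_source(p, theta_deg = 0)),
                       mode = mode)
  run_colony(cfg, taxis_params(n_cells = n_cells, n_steps = n_steps),
             seed = seed, record_stride = record_stride, ...)
}

# synthetic finger layout: clusters of cells beyond the rim at given
# transverse centres, each spanning `extent` in y, at x in (r_col, r_col+len]
finger_fixture <- function(centres_y, extent, r_col = 20, len = 10,
                           n_per = 9) {
  do.call(rbind, lapply(centres_y, function(cy) {
    cbind(x = r_col + seq(0.5, len, length.out = n_per),
          y = cy + seq(-extent / 2, extent / 2, length.out = n_per))
  }))
}
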