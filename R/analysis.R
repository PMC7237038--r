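#' Per-interval movement angles from a trajectory log
#'
#' For every cell and every consecutive pair of records spaced `interval`
#' steps apart, the angle (with the horizontal, in `[0, 2*pi)`) of the
#' displacement over that interval. Intervals with exactly zero displacement
#' are dropped; their count is attached as attribute `"n_dropped"`.
#'
#' @param log a `"trajectory_log"` (from [run_colony()]).
#' @param interval step interval; must be a positive multiple of the log's
#'   recording stride. Per-step angles (`interval = 1`) require a log
#'   recorded with stride 1.
#' @return Numeric vector of angles, pooled across cells.
#' @export
step_angles <- function(log, interval = log$record_stride) {
  if (interval < 1 || interval %% log$record_stride != 0)
    stop("interval must be a positive multiple of the recording stride (",
         log$record_stride, ")", call. = FALSE)
  sel <- which(log$times %% interval == 0)
  if (length(sel) < 2L)
    stop("log too short for this interval", call. = FALSE)
  x <- log$positions[sel, , 1L, drop = FALSE]
  y <- log$positions[sel, , 2L, drop = FALSE]
  nr <- length(sel)
  dx <- x[-1L, , 1L, drop = FALSE] - x[-nr, , 1L, drop = FALSE]
  dy <- y[-1L, , 1L, drop = FALSE] - y[-nr, , 1L, drop = FALSE]
  dx <- as.numeric(dx)
  dy <- as.numeric(dy)
  still <- dx == 0 & dy == 0
  ang <- norm_angle(atan2(dy[!still], dx[!still]))
  attr(ang, "n_dropped") <- sum(still)
  ang
}

#' Rose histogram of movement angles
#'
#' Counts angles in `n_bins` equal-width bins covering `[0, 2*pi)`, the first
#' bin starting at 0 (East).
#'
#' @param angles numeric vector of angles (radians; wrapped internally).
#' @param n_bins number of bins (>= 4); default 36 bins of 10 degrees.
#' @return An object of class `"rose_histogram"`: `bin_edges` (length
#'   `n_bins + 1`), `counts`, `n_total`.
#' @export
rose <- function(angles, n_bins = 36L) {
  if (n_bins < 4L) stop("n_bins must be >= 4", call. = FALSE)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  counts <- if (length(angles) == 0L) integer(n_bins) else
    tabulate(pmin(findInterval(norm_angle(angles), edges), n_bins),
             nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 n_total = length(angles)),
            class = "rose_histogram")
}

#' @export
print.rose_histogram <- function(x, ...) {
  n_bins <- length(x$counts)
  cat(sprintf("<rose_histogram> %d angles in %d bins of %.1f deg\n",
              x$n_total, n_bins, 360 / n_bins))
  if (x$n_total > 0) {
    k <- which.max(x$counts)
    cat(sprintf("  modal bin [%d, %d) deg: %d angles\n",
                round((k - 1) * 360 / n_bins), round(k * 360 / n_bins),
                x$counts[k]))
  }
  invisible(x)
}

#' @export
plot.rose_histogram <- function(x, col = "steelblue", ...) {
  n_bins <- length(x$counts)
  freq <- if (x$n_total > 0) x$counts / x$n_total else x$counts
  rmax <- max(freq, 1e-12)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  for (k in seq_len(n_bins)) {
    th <- seq(x$bin_edges[k], x$bin_edges[k + 1L], length.out = 8L)
    graphics::polygon(c(0, freq[k] * cos(th)), c(0, freq[k] * sin(th)),
                      col = col, border = "white")
  }
  invisible(x)
}

#' Circular resultant of a set of angles
#'
#' Mean direction and resultant length `Rbar = |sum(exp(i theta))| / n`:
#' 0 for uniformly spread headings, 1 for perfectly aligned ones.
#'
#' @param angles non-empty numeric vector of angles (radians).
#' @return List with `mean_angle` (radians, `NA` when `r = 0`) and `r`.
#' @export
resultant <- function(angles) {
  if (length(angles) == 0L) stop("no angles supplied", call. = FALSE)
  cx <- mean(cos(angles))
  sx <- mean(sin(angles))
  r <- sqrt(cx^2 + sx^2)
  list(mean_angle = if (r == 0) NA_real_ else norm_angle(atan2(sx, cx)),
       r = r)
}

# log von Mises density, stable for large kappa:
# log f = kappa*(cos(theta - mu) - 1) - log(2 pi) - log(I0(kappa) e^-kappa)
log_dvm <- function(cos_dev, kappa) {
  kappa * (cos_dev - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# ML fit of sum_k w_k VM(mu_k, kappa) + w_0 Uniform with fixed bearings mu,
# shared free kappa and free weights. Returns the maximised log-likelihood
# and the number of free parameters (K weights + kappa).
fit_vm_mixture <- function(angles, mus, kappa_max = 1e4) {
  n <- length(angles)
  if (length(mus) == 0L)
    return(list(loglik = -n * log(2 * pi), weights = 1, kappa = NA_real_,
                n_par = 0L))
  cos_dev <- vapply(mus, function(mu) cos(angles - mu), numeric(n))
  K <- length(mus)
  nll <- function(par) {
    w <- softmax(c(par[seq_len(K)], 0))
    kappa <- exp(par[K + 1L])
    if (!is.finite(kappa) || kappa > kappa_max) return(1e18)
    dens <- w[K + 1L] / (2 * pi)
    for (k in seq_len(K))
      dens <- dens + w[k] * exp(log_dvm(cos_dev[, k], kappa))
    -sum(log(dens))
  }
  start <- c(rep(-1, K), log(2))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  kappa <- exp(fit$par[K + 1L])
  if (kappa > 0.99 * kappa_max)
    stop("degenerate von Mises fit (kappa overflow); ",
         "increase the sample size", call. = FALSE)
  list(loglik = -fit$value,
       weights = softmax(c(fit$par[seq_len(K)], 0)), kappa = kappa,
       n_par = K + 1L)
}

#' Classify the information-integration mode from movement angles
#'
#' Fits two mixture models to a pooled sample of per-interval movement
#' angles, both with the source geometry held fixed and only the
#' concentration and mixing weights free:
#' \itemize{
#'   \item switching model: one von Mises component per source, centred on
#'     each source bearing, plus a uniform component (the random moves);
#'   \item vector model: a single von Mises centred on the vector-sum bearing
#'     plus a uniform component (pure uniform when the sources cancel
#'     exactly).
#' }
#' The label is the model with the lower AIC (the switching model has more
#' free weights, and with exactly cancelling sources the vector model is
#' nested inside it, so a complexity penalty is needed to avoid a spurious
#' switching call on uniform data); `delta_loglik` reports the raw
#' log-likelihood difference (switching minus vector). With a single source
#' the two models coincide and the margin is near zero.
#'
#' @param angles movement angles (radians); at least 1000 recommended.
#' @param sources list of [light_source()] with resolved bearings; at least
#'   2 for the comparison to be meaningful.
#' @param taxis_sign `+1` or `-1`; `-1` flips every model bearing by pi.
#' @return List of class `"mode_classification"`: `label` (either
#'   `"stochastic_switching"` or `"vector_integration"`), `delta_loglik`,
#'   and the two fits.
#' @export
classify_mode <- function(angles, sources, taxis_sign = 1) {
  if (length(angles) < 2L) stop("too few angles", call. = FALSE)
  flip <- if (taxis_sign == -1) pi else 0
  mus_switch <- vapply(sources, function(s) norm_angle(s$theta - flip),
                       numeric(1L))
  vs <- vector_sum(sources)
  mus_vec <- if (vs$p_vec == 0) numeric(0) else
    norm_angle(vs$theta_vec - flip)
  fit_s <- fit_vm_mixture(angles, mus_switch)
  fit_v <- fit_vm_mixture(angles, mus_vec)
  delta <- fit_s$loglik - fit_v$loglik
  aic_s <- 2 * fit_s$n_par - 2 * fit_s$loglik
  aic_v <- 2 * fit_v$n_par - 2 * fit_v$loglik
  structure(list(
    label = if (aic_s < aic_v) "stochastic_switching" else
      "vector_integration",
    delta_loglik = delta, fit_switching = fit_s, fit_vector = fit_v),
    class = "mode_classification")
}

#' @export
print.mode_classification <- function(x, ...) {
  cat(sprintf("<mode_classification> %s (delta logLik %.1f)\n",
              x$label, x$delta_loglik))
  invisible(x)
}

#' Finger morphometrics of a final colony configuration
#'
#' Segments the cells that have left the initial colony disc along the light
#' bearing into fingers, and measures their geometry. Coordinates are rotated
#' so the light bearing points along +x; cells with `x > R_col` (beyond the
#' rim) are sorted by their transverse coordinate `y` and split into clusters
#' wherever the gap between consecutive cells exceeds `gap_threshold`. Per
#' cluster, width is the `y`-extent plus one cell diameter and length the
#' maximal `x` beyond the rim; separation is the mean distance between
#' adjacent cluster centres.
#'
#' @param positions `N x 2` matrix of final cell centres.
#' @param centre colony centre at t = 0.
#' @param r_col initial colony radius.
#' @param bearing light bearing (radians); for negative phototaxis pass the
#'   anti-source bearing.
#' @param gap_threshold transverse gap splitting two fingers (default one
#'   cell diameter).
#' @param radius cell radius.
#' @return An object of class `"finger_metrics"`: `n_fingers`, `mean_width`,
#'   `mean_separation`, `width_sep_ratio`, `mean_length`, `orientation`
#'   (circular mean bearing of finger centroids from the colony centre), and
#'   the per-finger table `fingers`.
#' @export
finger_metrics <- function(positions, centre, r_col, bearing,
                           gap_threshold = 2, radius = 1) {
  positions <- as_positions(positions)
  rel <- sweep(positions, 2L, as.numeric(centre))
  xr <- cos(-bearing) * rel[, 1L] - sin(-bearing) * rel[, 2L]
  yr <- sin(-bearing) * rel[, 1L] + cos(-bearing) * rel[, 2L]
  out_sel <- xr > r_col
  empty <- structure(list(n_fingers = 0L, mean_width = NA_real_,
                          mean_separation = NA_real_,
                          width_sep_ratio = NA_real_,
                          mean_length = NA_real_, orientation = NA_real_,
                          fingers = data.frame()),
                     class = "finger_metrics")
  if (!any(out_sel)) return(empty)
  xo <- xr[out_sel]
  yo <- yr[out_sel]
  ord <- order(yo)
  yo <- yo[ord]
  xo <- xo[ord]
  cl <- cumsum(c(1, diff(yo) > gap_threshold))
  fingers <- do.call(rbind, lapply(split(seq_along(yo), cl), function(ix) {
    data.frame(n_cells = length(ix),
               centre_y = mean(yo[ix]),
               width = diff(range(yo[ix])) + 2 * radius,
               length = max(xo[ix]) - r_col,
               centroid_x = mean(xo[ix]))
  }))
  rownames(fingers) <- NULL
  nf <- nrow(fingers)
  sep <- if (nf >= 2L) mean(diff(fingers$centre_y)) else NA_real_
  # finger bearings from the colony centre, in the original frame
  cen_ang <- atan2(fingers$centre_y, fingers$centroid_x) + bearing
  ori <- resultant(cen_ang)$mean_angle
  structure(list(n_fingers = nf, mean_width = mean(fingers$width),
                 mean_separation = sep,
                 width_sep_ratio = if (is.na(sep)) NA_real_ else
                   mean(fingers$width) / sep,
                 mean_length = mean(fingers$length), orientation = ori,
                 fingers = fingers),
            class = "finger_metrics")
}

#' @export
print.finger_metrics <- function(x, ...) {
  cat(sprintf("<finger_metrics> %d finger(s)\n", x$n_fingers))
  if (x$n_fingers > 0)
    cat(sprintf(
      "  mean width %.2f, separation %.2f (ratio %.2f), length %.2f\n",
      x$mean_width, x$mean_separation, x$width_sep_ratio, x$mean_length))
  invisible(x)
}

#' Advance speed of the colony front
#'
#' Tracks the maximal projected extent of the cells along the light bearing
#' over time, and fits a least-squares line to the records after the front
#' first leaves the colony rim. The slope is the front speed (R per step);
#' the residual RMS measures how constant that speed is.
#'
#' @param log a `"trajectory_log"`.
#' @param bearing light bearing (radians).
#' @param r_col initial colony radius.
#' @param centre colony centre at t = 0.
#' @param min_records minimum number of post-egress records for a fit.
#' @return List: `speed` (`NA` when the front never leaves the rim), `rms`,
#'   `t_egress`, and the `extent` series (data frame `time`, `extent`).
#' @export
front_speed <- function(log, bearing, r_col, centre = c(0, 0),
                        min_records = 10L) {
  nr <- dim(log$positions)[1L]
  px <- matrix(log$positions[, , 1L], nrow = nr) - centre[1L]
  py <- matrix(log$positions[, , 2L], nrow = nr) - centre[2L]
  proj <- px * cos(bearing) + py * sin(bearing)
  extent <- apply(proj, 1L, max)
  series <- data.frame(time = log$times, extent = extent)
  out <- which(extent > r_col)
  if (length(out) == 0L || (length(log$times) - out[1L] + 1L) < min_records)
    return(list(speed = NA_real_, rms = NA_real_, t_egress = NA_integer_,
                extent = series))
  win <- seq.int(out[1L], length(log$times))
  fit <- stats::lm(extent ~ time, data = series[win, ])
  list(speed = unname(stats::coef(fit)[2L]),
       rms = sqrt(mean(stats::residuals(fit)^2)),
       t_egress = log$times[out[1L]], extent = series)
}

#' Calibrate the simulation time step against real units
#'
#' An isolated cell on saturated slime covers `max_speed_sim` cell radii per
#' step; matching that against a measured gliding speed fixes the physical
#' duration of one step: `dt = max_speed_sim * cell_radius_um /
#' measured_speed_um_s`. With the default model speed 0.1 R/step, a 1 micron
#' cell radius and the measured 0.1 micron/s gliding speed, one step is one
#' second.
#'
#' @param max_speed_sim maximum cell speed in the model, R per step.
#' @param cell_radius_um cell radius in microns.
#' @param measured_speed_um_s measured gliding speed in microns per second.
#' @return Seconds per simulation step.
#' @examples
#' calibrate_dt(0.1, 1, 0.1)         # 1 second per step
#' steps_to_hours(1e5, 1)            # ~27.8 hours
#' @export
calibrate_dt <- function(max_speed_sim = 0.1, cell_radius_um = 1,
                         measured_speed_um_s = 0.1) {
  if (measured_speed_um_s <= 0 || cell_radius_um <= 0 || max_speed_sim <= 0)
    stop("calibration inputs must be positive", call. = FALSE)
  max_speed_sim * cell_radius_um / measured_speed_um_s
}

#' @rdname calibrate_dt
#' @param n_steps number of simulation steps.
#' @param dt_s seconds per step.
#' @return `steps_to_hours`: duration in hours.
#' @export
steps_to_hours <- function(n_steps, dt_s) n_steps * dt_s / 3600
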