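#' Colony configuration
#'
#' Describes one colony: where it sits, how many cells and at what areal
#' density, the mixture of cell types (wavelength sensitivity and phototaxis
#' sign), the light sources it perceives, and the information-integration
#' mode. Source bearings and probabilities are resolved once from the initial
#' colony centre; intensity is uniform within a colony.
#'
#' @param centre 2-D colony centre.
#' @param n_cells,density override the parameter-set values of N and rho
#'   (`NULL` = use `params`).
#' @param composition data frame with columns `sensitivity` (tag),
#'   `fraction` (summing to 1) and `taxis_sign` (+1/-1); cell counts are the
#'   fractions rounded to integers by largest remainder.
#' @param sources list of [light_source()].
#' @param mode `"single"`, `"stochastic_switching"` or `"vector_integration"`.
#' @param grid_dim slime lattice dimension `c(rows, cols)`; spacing is one
#'   cell radius and the lattice is centred on the colony.
#' @param deposit_premove deposit slime at the pre-move position instead of
#'   the post-move position.
#' @param reciprocal apply reaction forces on pili pullers.
#' @return An object of class `"colony_config"`.
#' @export
colony_config <- function(centre = c(0, 0), n_cells = NULL, density = NULL,
                          composition = NULL, sources = list(),
                          mode = c("stochastic_switching", "single",
                                   "vector_integration"),
                          grid_dim = c(300L, 300L),
                          deposit_premove = FALSE, reciprocal = FALSE) {
  mode <- match.arg(mode)
  if (is.null(composition))
    composition <- data.frame(sensitivity = "all", fraction = 1,
                              taxis_sign = 1)
  stopifnot(all(c("sensitivity", "fraction", "taxis_sign") %in%
                  names(composition)))
  if (abs(sum(composition$fraction) - 1) > 1e-8)
    stop("composition fractions must sum to 1", call. = FALSE)
  if (!all(composition$taxis_sign %in% c(-1, 1)))
    stop("taxis_sign must be +1 or -1", call. = FALSE)
  cfg <- list(centre = as.numeric(centre), n_cells = n_cells,
              density = density, composition = composition,
              sources = sources, mode = mode,
              grid_dim = as.integer(grid_dim),
              deposit_premove = isTRUE(deposit_premove),
              reciprocal = isTRUE(reciprocal))
  class(cfg) <- "colony_config"
  cfg
}

# integer class counts from fractions by largest remainder
composition_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# resolve source bearings against a colony centre and build one decision
# table per cell class (sensitivity x taxis_sign combination present)
resolve_classes <- function(config) {
  sources <- lapply(config$sources, function(s) {
    if (is.null(s$theta)) s$theta <- source_bearing(config$centre, s$position)
    s
  })
  comp <- config$composition
  tables <- vector("list", nrow(comp))
  for (k in seq_len(nrow(comp)))
    tables[[k]] <- decision_table(
      visible_sources(comp$sensitivity[k], sources),
      config$mode, comp$taxis_sign[k])
  list(sources = sources, tables = tables)
}

#' Initialise a colony
#'
#' Places `N` cells uniformly at random on a disc of radius
#' `R_col = R * sqrt(N / rho)` (so the areal density `N R^2 / R_col^2` equals
#' `rho`), assigns cell types by shuffling to match the composition counts,
#' and lays down a slime lattice (spacing `R`, centred on the colony) at
#' level `s0` under the disc and 0 outside. Source bearings and the per-class
#' heading decision tables are resolved here, from the t = 0 centre.
#'
#' @param config a [colony_config()].
#' @param params a [taxis_params()].
#' @param seed optional seed applied via [set.seed()].
#' @return An object of class `"simulation_state"`: fields `t`, `positions`,
#'   `sensitivity`, `taxis_sign`, `cell_class`, `class_tables`, `slime`,
#'   `r_col`, `config`, `params`.
#' @export
init_colony <- function(config, params = taxis_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.null(config$n_cells)) params$n_cells else
    as.integer(config$n_cells)
  rho <- if (is.null(config$density)) params$rho else config$density
  r_col <- params$radius * sqrt(n / rho)
  half_x <- (config$grid_dim[2L] - 1L) * params$radius / 2
  half_y <- (config$grid_dim[1L] - 1L) * params$radius / 2
  if (r_col > half_x || r_col > half_y)
    stop("colony disc does not fit inside the slime lattice; ",
         "increase grid_dim", call. = FALSE)

  rad <- r_col * sqrt(stats::runif(n))
  ang <- 2 * pi * stats::runif(n)
  positions <- cbind(config$centre[1L] + rad * cos(ang),
                     config$centre[2L] + rad * sin(ang))

  comp <- config$composition
  counts <- composition_counts(comp$fraction, n)
  cell_class <- sample(rep.int(seq_len(nrow(comp)), counts))

  grid <- slime_grid(dim = config$grid_dim, spacing = params$radius,
                     origin = c(config$centre[1L] - half_x,
                                config$centre[2L] - half_y),
                     value = 0, s_rate = params$s_rate,
                     s_max = params$s_max, s0 = params$s0)
  gx <- grid$origin[1L] + (seq_len(ncol(grid$values)) - 1) * grid$spacing
  gy <- grid$origin[2L] + (seq_len(nrow(grid$values)) - 1) * grid$spacing
  # inflate the disc by half a lattice diagonal so that the nearest lattice
  # point of every in-disc cell is slimed (rim cells would otherwise start
  # over bare points through rounding alone)
  r_slime <- r_col + grid$spacing * sqrt(2) / 2
  inside <- outer((gy - config$centre[2L])^2, (gx - config$centre[1L])^2,
                  "+") <= r_slime^2
  grid$values[inside] <- params$s0

  rc <- resolve_classes(config)
  state <- list(t = 0L, positions = positions,
                sensitivity = comp$sensitivity[cell_class],
                taxis_sign = comp$taxis_sign[cell_class],
                cell_class = cell_class, class_tables = rc$tables,
                sources = rc$sources, slime = grid, r_col = r_col,
                config = config, params = params)
  class(state) <- "simulation_state"
  state
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> t = %d, %d cells, colony radius %.2f\n",
              x$t, nrow(x$positions), x$r_col))
  cat(sprintf("  mode %s, %d source(s); slime lattice %d x %d\n",
              x$config$mode, length(x$sources), nrow(x$slime$values),
              ncol(x$slime$values)))
  invisible(x)
}

#' Advance a colony by one step (reference implementation)
#'
#' Pure-R single update step, bit-identical to the compiled run loop under
#' the same RNG stream. Using positions at time `t` only: (1) every cell
#' draws a heading (branch draw, then angle draw, ascending cell order) and
#' gets its propulsion `G_i`; (2) pili attachments are sampled (ascending
#' puller order) and forces `F_i` accumulated; (3) each cell moves by
#' `(G_i + F_i) * S / (gamma0 * s0)` with `S` the slime at the lattice point
#' nearest its time-`t` position (zero motion where `S = 0`); (4) positions
#' commit in parallel; (5) every cell deposits `s_rate` at its new nearest
#' lattice point (old, if `deposit_premove`).
#'
#' @param state a `"simulation_state"`.
#' @param draws optional pre-drawn randomness, a list with `u` (a `2 x N`
#'   matrix of branch/angle uniforms) and `att` (per-cell numeric vectors of
#'   `m` selection uniforms); when supplied the global RNG is untouched.
#' @return The updated state (`t` incremented).
#' @export
step_state <- function(state, draws = NULL) {
  p <- state$params
  cfg <- state$config
  pos <- state$positions
  n <- nrow(pos)

  u <- if (is.null(draws)) matrix(stats::runif(2L * n), nrow = 2L) else
    draws$u
  heading <- 2 * pi * u[2L, ]
  for (k in seq_along(state$class_tables)) {
    tab <- state$class_tables[[k]]
    sel <- which(state$cell_class == k)
    if (length(tab$cump)) {
      br <- branch_from_u(u[1L, sel], tab$cump)
      heading[sel[br > 0L]] <- tab$theta[br[br > 0L]]
    }
  }
  G <- propulsion_force(heading, p$f0)

  nbr <- neighbour_lists(pos, p$ell)
  pullers <- integer(0)
  targets <- integer(0)
  for (j in seq_len(n)) {
    nb <- nbr[[j]]
    nn <- length(nb)
    if (nn == 0L) next
    if (nn <= p$m) {
      chosen <- nb
    } else {
      us <- if (is.null(draws)) stats::runif(p$m) else draws$att[[j]]
      idx <- nb
      chosen <- integer(p$m)
      for (tt in seq_len(p$m)) {
        r <- tt + floor(us[tt] * (nn - tt + 1))
        if (r > nn) r <- nn
        tmp <- idx[tt]; idx[tt] <- idx[r]; idx[r] <- tmp
        chosen[tt] <- idx[tt]
      }
    }
    pullers <- c(pullers, rep.int(j, length(chosen)))
    targets <- c(targets, chosen)
  }
  F <- accumulate_forces(data.frame(puller = pullers, target = targets),
                         pos, p, reciprocal = cfg$reciprocal)

  rc <- nearest_grid_point(pos, state$slime)
  S <- state$slime$values[rc]
  mob <- S / (p$gamma0 * p$s0)
  new_pos <- pos + (G + F) * mob
  if (any(!is.finite(new_pos)))
    stop("non-finite position", call. = FALSE)

  state$slime <- deposit(state$slime,
                         if (cfg$deposit_premove) pos else new_pos)
  state$positions <- new_pos
  state$t <- state$t + 1L
  state
}

#' Run a colony simulation
#'
#' Initialises a colony and iterates the update step `n_steps` times in
#' compiled code, recording positions every `record_stride` steps (t = 0 and
#' the final step are always recorded). Repeating a run with the same
#' configuration and seed reproduces it record-for-record.
#'
#' @param config a [colony_config()].
#' @param params a [taxis_params()]; `n_steps` and (by default) `seed` are
#'   taken from here.
#' @param record_stride steps between trajectory records.
#' @param record_cells indices of the cells to record (default all); the
#'   final state always covers all cells.
#' @param seed integer seed (default `params$seed`).
#' @param n_steps override `params$n_steps`.
#' @return A list of class `"colony_run"`: `log` (a `"trajectory_log"`) and
#'   `state` (the final `"simulation_state"`).
#' @examples
#' cfg <- colony_config(sources = list(light_source(0.05, theta_deg = 0)))
#' run <- run_colony(cfg, taxis_params(n_cells = 50, n_steps = 200), seed = 1)
#' run$log
#' @export
run_colony <- function(config, params = taxis_params(), record_stride = 100L,
                       record_cells = NULL, seed = params$seed,
                       n_steps = params$n_steps) {
  set.seed(seed)
  state <- init_colony(config, params)
  n <- nrow(state$positions)
  if (is.null(record_cells)) record_cells <- seq_len(n)
  record_steps <- unique(c(seq.int(0L, n_steps, by = record_stride),
                           n_steps))
  tables <- state$class_tables
  res <- simulate_colony_cpp(
    state$positions, state$cell_class,
    lapply(tables, `[[`, "cump"), lapply(tables, `[[`, "theta"),
    state$slime$values, state$slime$origin, state$slime$spacing,
    unclass(params), as.integer(n_steps), as.integer(record_steps),
    as.integer(record_cells), config$deposit_premove, config$reciprocal)

  state$positions <- res$final_positions
  state$slime$values <- res$slime
  state$t <- as.integer(n_steps)
  log <- structure(list(times = record_steps, positions = res$traj,
                        cell_ids = record_cells,
                        record_stride = as.integer(record_stride),
                        sensitivity = state$sensitivity[record_cells],
                        taxis_sign = state$taxis_sign[record_cells]),
                   class = "trajectory_log")
  structure(list(log = log, state = state), class = "colony_run")
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat(sprintf(
    "<trajectory_log> %d records (t = %d..%d, stride %d), %d cells\n",
    length(x$times), x$times[1L], x$times[length(x$times)],
    x$record_stride, dim(x$positions)[2L]))
  invisible(x)
}

#' @export
print.colony_run <- function(x, ...) {
  print(x$state)
  print(x$log)
  invisible(x)
}

#' Run several independent colonies
#'
#' Simulates a list of colony configurations as independent systems, each on
#' its own slime lattice, with per-colony RNG substreams derived from the
#' master seed (so any colony's trajectory is reproducible in isolation).
#'
#' @param configs list of [colony_config()].
#' @param params a [taxis_params()].
#' @param seed master seed.
#' @param record_stride,record_cells,n_steps as in [run_colony()].
#' @return A list of `"colony_run"`, one per configuration.
#' @export
run_experiment <- function(configs, params = taxis_params(),
                           seed = params$seed, record_stride = 100L,
                           record_cells = NULL, n_steps = params$n_steps) {
  set.seed(seed)
  sub <- sample.int(2147483646L, length(configs))
  out <- vector("list", length(configs))
  for (k in seq_along(configs))
    out[[k]] <- run_colony(configs[[k]], params,
                           record_stride = record_stride,
                           record_cells = record_cells, seed = sub[k],
                           n_steps = n_steps)
  names(out) <- names(configs)
  out
}

#' Plot a colony state
#'
#' Draws the slime lattice as a grey-scale image (darker = more slime) with
#' cells overlaid as green discs, the standard visual convention for these
#' simulations.
#'
#' @param x a `"simulation_state"`.
#' @param zoom optional plot half-width around the colony centre (default:
#'   whole lattice).
#' @param ... passed to [graphics::points()].
#' @return `x`, invisibly.
#' @export
plot.simulation_state <- function(x, zoom = NULL, ...) {
  g <- x$slime
  gx <- g$origin[1L] + (seq_len(ncol(g$values)) - 1) * g$spacing
  gy <- g$origin[2L] + (seq_len(nrow(g$values)) - 1) * g$spacing
  graphics::image(gx, gy, t(g$values), col = grDevices::grey.colors(
    64, start = 1, end = 0.3), asp = 1, xlab = "x (R)", ylab = "y (R)",
    main = sprintf("t = %d", x$t),
    xlim = if (is.null(zoom)) range(gx) else x$config$centre[1L] + c(-1, 1) *
      zoom,
    ylim = if (is.null(zoom)) range(gy) else x$config$centre[2L] + c(-1, 1) *
      zoom)
  graphics::points(x$positions, pch = 16, cex = 0.4, col = "darkgreen", ...)
  invisible(x)
}
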