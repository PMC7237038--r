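#' Slime lattice
#'
#' A regular square lattice carrying the amount of extruded polysaccharide
#' (slime) at each point. Slime never decays or diffuses; cells deposit
#' `s_rate` per step at the lattice point nearest their centre, capped at
#' `s_max`, and experience a friction `gamma0 * s0 / S` set by the slime under
#' them. Lattice point `(r, c)` (1-based row, column) sits at world
#' coordinate `origin + spacing * (c - 1, r - 1)`: rows index y, columns x.
#'
#' @param dim lattice dimension, `c(n_rows, n_cols)`.
#' @param spacing lattice constant, in length units (default one cell radius).
#' @param origin world coordinate of lattice point (1, 1).
#' @param value initial slime level at every point.
#' @param s_rate,s_max,s0 deposition rate, cap, and in-colony reference level.
#' @return An object of class `"slime_grid"`.
#' @export
slime_grid <- function(dim = c(300L, 300L), spacing = 1,
                       origin = c(0, 0), value = 0,
                       s_rate = 0.1, s_max = 1, s0 = 1) {
  stopifnot(length(dim) == 2L, all(dim >= 1L), spacing > 0,
            s_rate > 0, s_max >= s0, s0 > 0, value >= 0, value <= s_max)
  g <- list(values = matrix(value, nrow = dim[1L], ncol = dim[2L]),
            spacing = spacing, origin = as.numeric(origin),
            s_rate = s_rate, s_max = s_max, s0 = s0)
  class(g) <- "slime_grid"
  g
}

#' @export
print.slime_grid <- function(x, ...) {
  cat(sprintf("<slime_grid> %d x %d, spacing %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$spacing,
              x$origin[1L], x$origin[2L]))
  cat(sprintf("  slime range [%g, %g], cap %g, rate %g\n",
              min(x$values), max(x$values), x$s_max, x$s_rate))
  invisible(x)
}

#' Nearest lattice point to a position
#'
#' Rounds a world position to the nearest lattice point. Exact half-spacing
#' ties round toward `+Inf` on each axis.
#'
#' @param position a 2-D world coordinate `(x, y)`, or an `N x 2` matrix.
#' @param grid a [slime_grid()].
#' @return An integer `(row, col)` pair (1-based; row indexes y, col indexes
#'   x), or an `N x 2` integer matrix for matrix input.
#' @examples
#' g <- slime_grid(dim = c(20, 20))
#' nearest_grid_point(c(10.2, 7.8), g)   # lattice point at world (10, 8)
#' @export
nearest_grid_point <- function(position, grid) {
  pos <- if (is.matrix(position)) position else matrix(position, 1L, 2L)
  cc <- floor((pos[, 1L] - grid$origin[1L]) / grid$spacing + 0.5) + 1
  rr <- floor((pos[, 2L] - grid$origin[2L]) / grid$spacing + 0.5) + 1
  if (any(rr < 1 | rr > nrow(grid$values) | cc < 1 | cc > ncol(grid$values)))
    stop("position outside the slime lattice", call. = FALSE)
  out <- cbind(row = as.integer(rr), col = as.integer(cc))
  if (is.matrix(position)) out else out[1L, ]
}

#' World coordinate of a lattice point
#'
#' @param rc integer `(row, col)` pair or `N x 2` matrix.
#' @param grid a [slime_grid()].
#' @return The `(x, y)` world coordinate(s).
#' @export
grid_point_position <- function(rc, grid) {
  rc <- if (is.matrix(rc)) rc else matrix(rc, 1L, 2L)
  out <- cbind(grid$origin[1L] + (rc[, 2L] - 1) * grid$spacing,
               grid$origin[2L] + (rc[, 1L] - 1) * grid$spacing)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Deposit slime under cells
#'
#' Adds `s_rate` at the lattice point nearest each supplied position, capped
#' at `s_max`. Several cells over the same point each deposit; the cap applies
#' after every increment (equivalently, `min(S + k * s_rate, s_max)` for `k`
#' cells).
#'
#' @param grid a [slime_grid()].
#' @param positions a 2-D coordinate or `N x 2` matrix of cell centres.
#' @return The updated grid.
#' @export
deposit <- function(grid, positions) {
  pos <- if (is.matrix(positions)) positions else matrix(positions, 1L, 2L)
  rc <- nearest_grid_point(pos, grid)
  lin <- rc[, 1L] + (rc[, 2L] - 1L) * nrow(grid$values)
  counts <- table(lin)
  idx <- as.integer(names(counts))
  grid$values[idx] <- pmin(grid$values[idx] +
                             as.integer(counts) * grid$s_rate, grid$s_max)
  grid
}

#' Slime-dependent friction
#'
#' The friction factor entering the overdamped update,
#' `gamma = gamma0 * s0 / S`. On bare substrate (`S = 0`) friction is
#' infinite: the displacement contract is zero motion, and `Inf` is returned.
#'
#' @param S slime level(s).
#' @param params a [taxis_params()] object (uses `gamma0`, `s0`).
#' @return Friction value(s); `Inf` where `S = 0`.
#' @examples
#' friction(1, taxis_params())     # gamma0 = 10: step f0/gamma = 0.1 R
#' friction(0, taxis_params())     # Inf: no motion off the slime
#' @export
friction <- function(S, params = taxis_params()) {
  if (any(S < 0)) stop("slime levels must be >= 0", call. = FALSE)
  ifelse(S > 0, params$gamma0 * params$s0 / S, Inf)
}

#' Write or read a slime grid snapshot
#'
#' The lattice is stored as a dense CSV matrix (rows = lattice rows) with a
#' JSON sidecar (`<path>.json`) recording spacing, origin and the slime
#' constants.
#'
#' @param grid a [slime_grid()].
#' @param path CSV file path.
#' @return `write_slime` returns `path` invisibly; `read_slime` the grid.
#' @export
write_slime <- function(grid, path) {
  utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(spacing = grid$spacing, origin = grid$origin,
               s_rate = grid$s_rate, s_max = grid$s_max, s0 = grid$s0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slime
#' @export
read_slime <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- slime_grid(dim = dim(values), spacing = meta$spacing,
                  origin = meta$origin, s_rate = meta$s_rate,
                  s_max = meta$s_max, s0 = meta$s0)
  g$values <- values
  g
}
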