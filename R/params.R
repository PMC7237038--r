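#' Simulation parameter set
#'
#' Construct the full parameter set of the colony model. Defaults are the
#' published simulation values: `N = 500` cells of radius `R = 1` at areal
#' density `rho = 0.1`, `m = 4` pili of reach `ell = 4R` per cell, force-kernel
#' constants `(k1, k2) = (1, 2)`, baseline friction `gamma0 = 1/(0.1 R)` (so an
#' isolated cell on saturated slime moves at most 0.1 body lengths per step),
#' slime deposition rate `s_rate = 0.1`, and phototaxis probability
#' `p_photo = 0.05` (the top of the published `(0, 0.05]` range).
#'
#' `s0` and `s_max` are the initial in-colony and maximum slime level; the
#' default `s0 = s_max = 1` starts the colony interior saturated, so the
#' maximum speed `f0/gamma0 = 0.1 R` is attained at `t = 0` and can never be
#' exceeded (the friction factor is `gamma0 * s0 / S >= gamma0` for
#' `S <= s_max`).
#'
#' @param n_cells number of cells N.
#' @param radius cell radius R; the model's length unit.
#' @param rho colony areal density, `N R^2 / R_col^2`, in (0, 1].
#' @param ell maximum pilus reach (centre-to-centre), in length units.
#' @param m number of pili per cell.
#' @param gamma0 baseline friction (inverse speed) on slime level `s0`.
#' @param k1,k2 shape constants of the pili force kernel.
#' @param s_rate slime deposited per cell per step.
#' @param s0 initial slime level under the colony.
#' @param s_max slime cap; deposition never raises a lattice point above it.
#' @param f0 propulsion force magnitude.
#' @param p_photo probability per step of a directed move (single source).
#' @param n_steps number of update steps in a run.
#' @param seed integer RNG seed.
#' @return An object of class `"taxis_params"` (a validated named list).
#' @examples
#' p <- taxis_params()
#' p$gamma0            # 10 = 1 / (0.1 * R)
#' taxis_params(p_photo = 0.01, n_steps = 1e4)
#' @export
taxis_params <- function(n_cells = 500L, radius = 1, rho = 0.1, ell = 4,
                         m = 4L, gamma0 = 1 / (0.1 * radius), k1 = 1, k2 = 2,
                         s_rate = 0.1, s0 = 1, s_max = 1, f0 = 1,
                         p_photo = 0.05, n_steps = 40000L, seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), radius = radius, rho = rho,
            ell = ell, m = as.integer(m), gamma0 = gamma0, k1 = k1, k2 = k2,
            s_rate = s_rate, s0 = s0, s_max = s_max, f0 = f0,
            p_photo = p_photo, n_steps = as.integer(n_steps),
            seed = as.integer(seed))
  class(p) <- "taxis_params"
  validate_params(p)
  p
}

#' Default parameter set
#'
#' The published simulation parameters; equivalent to [taxis_params()] with no
#' arguments.
#' @return A `"taxis_params"` object.
#' @export
default_params <- function() taxis_params()

validate_params <- function(p) {
  stopifnot(inherits(p, "taxis_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg,
                                                 call. = FALSE)
  chk(is.finite(p$radius) && p$radius > 0, "radius must be > 0")
  chk(is.finite(p$ell) && p$ell > 0, "ell must be > 0")
  chk(p$n_cells >= 1L, "n_cells must be >= 1")
  chk(p$m >= 1L, "m must be >= 1")
  chk(is.finite(p$rho) && p$rho > 0 && p$rho <= 1, "rho must be in (0, 1]")
  chk(is.finite(p$p_photo) && p$p_photo >= 0 && p$p_photo <= 1,
      "p_photo must be in [0, 1]")
  chk(is.finite(p$gamma0) && p$gamma0 > 0, "gamma0 must be > 0")
  chk(is.finite(p$s_rate) && p$s_rate > 0, "s_rate must be > 0")
  chk(is.finite(p$s0) && is.finite(p$s_max) && p$s_max >= p$s0 && p$s0 > 0,
      "need s_max >= s0 > 0")
  chk(is.finite(p$f0) && p$f0 >= 0, "f0 must be >= 0")
  chk(p$n_steps >= 0L, "n_steps must be >= 0")
  chk(!is.na(p$seed), "seed must be an integer")
  invisible(p)
}

#' @export
print.taxis_params <- function(x, ...) {
  cat("Colony model parameters\n")
  cat(sprintf("  N = %d cells, R = %g, rho = %g (colony radius %.2f R)\n",
              x$n_cells, x$radius, x$rho,
              sqrt(x$n_cells / x$rho)))
  cat(sprintf("  pili: m = %d, reach ell = %g; kernel (k1, k2) = (%g, %g)\n",
              x$m, x$ell, x$k1, x$k2))
  cat(sprintf("  friction gamma0 = %g, propulsion f0 = %g (max step %.3g R)\n",
              x$gamma0, x$f0, x$f0 / x$gamma0))
  cat(sprintf("  slime: s_rate = %g, s0 = %g, s_max = %g\n",
              x$s_rate, x$s0, x$s_max))
  cat(sprintf("  p_photo = %g, n_steps = %d, seed = %d\n",
              x$p_photo, x$n_steps, x$seed))
  invisible(x)
}

#' Write or read a parameter set as YAML or JSON
#'
#' Round-trips a [taxis_params()] object through a flat config block whose keys
#' are the ASCII parameter names (`n_cells`, `radius`, `rho`, `ell`, `m`,
#' `gamma0`, `k1`, `k2`, `s_rate`, `s0`, `s_max`, `f0`, `p_photo`, `n_steps`,
#' `seed`). The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param params a `"taxis_params"` object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   validated `"taxis_params"` object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  do.call(taxis_params, x)
}
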