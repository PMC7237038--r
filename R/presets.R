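#' Experiment presets
#'
#' Ready-made multi-colony experiment recipes reproducing the standard
#' simulation layouts:
#' \describe{
#'   \item{`linear_array`}{5 colonies illuminated by a single source to the
#'     East; the directed-move probability decreases linearly from `p_ref` at
#'     the easternmost colony to `p_min` at the westernmost (intensity falls
#'     off with distance).}
#'   \item{`grid_switching`, `grid_vector`}{a 5 x 5 grid of colonies with two
#'     sources, one North and one East of the grid, each one grid unit beyond
#'     it; per-colony probabilities follow the inverse-distance law,
#'     normalised so the colony nearest each source receives `p_ref`. The two
#'     variants differ only in the integration mode.}
#'   \item{`rose_pairs`}{one colony with two equal sources placed
#'     `separation_deg` North and South of East, `p1 = p2 = p_ref`; the
#'     layout for rose-plot and classifier studies.}
#'   \item{`mixed_wavelength`}{the `rose_pairs` geometry with a red source
#'     North of East and a green one South of East, and a colony mixing
#'     red-sensitive and green-sensitive cells in a given ratio.}
#'   \item{`negative_uv`}{the `linear_array` layout under a UV source that
#'     repels the cells (`taxis_sign = -1`).}
#' }
#'
#' @param name preset name (see above).
#' @param separation_deg half-angle between the paired sources and the E-W
#'   axis (rose/mixed presets): sources sit at `+separation_deg` and
#'   `-separation_deg`.
#' @param mode integration mode for the `rose_pairs` preset.
#' @param ratio `c(red, green)` cell proportions for `mixed_wavelength`
#'   (normalised internally).
#' @param p_ref reference (maximum) directed-move probability.
#' @param p_min probability floor of the linear intensity profile.
#' @param n_colonies number of colonies in the linear arrays.
#' @param grid_n side of the colony grid in the grid presets.
#' @param params base [taxis_params()]; per-colony probabilities live in the
#'   sources, everything else here.
#' @param grid_dim slime lattice dimension per colony. The preset default
#'   (700 x 700) leaves room for the full front advance of a 4e4-step run
#'   (about 0.5 R per 100 steps beyond the rim); shrink it for short runs.
#' @return An object of class `"experiment_preset"`: `name`, `colonies`
#'   (list of [colony_config()]), `params`, and a `meta` list describing the
#'   resolved geometry.
#' @examples
#' pre <- build_preset("linear_array")
#' sapply(pre$colonies, function(cc) cc$sources[[1]]$p)  # 0.05 ... 0.01
#' @export
build_preset <- function(name = c("linear_array", "grid_switching",
                                  "grid_vector", "rose_pairs",
                                  "mixed_wavelength", "negative_uv"),
                         separation_deg = 60, mode = "stochastic_switching",
                         ratio = c(red = 0.5, green = 0.5), p_ref = 0.05,
                         p_min = 0.01, n_colonies = 5L, grid_n = 5L,
                         params = taxis_params(),
                         grid_dim = c(700L, 700L)) {
  name <- match.arg(name)
  out <- switch(
    name,
    linear_array = preset_linear(p_ref, p_min, n_colonies, taxis_sign = 1,
                                 wavelength = "red", grid_dim = grid_dim),
    negative_uv = preset_linear(p_ref, p_min, n_colonies, taxis_sign = -1,
                                wavelength = "UV", grid_dim = grid_dim),
    grid_switching = preset_grid(p_ref, grid_n, "stochastic_switching",
                                 grid_dim),
    grid_vector = preset_grid(p_ref, grid_n, "vector_integration", grid_dim),
    rose_pairs = preset_pair(p_ref, separation_deg, mode, grid_dim),
    mixed_wavelength = preset_mixed(p_ref, separation_deg, ratio, grid_dim))
  structure(list(name = name, colonies = out$colonies, params = params,
                 meta = out$meta),
            class = "experiment_preset")
}

preset_linear <- function(p_ref, p_min, n_colonies, taxis_sign, wavelength,
                          grid_dim) {
  # colony 1 is easternmost (nearest the source); p decreases linearly
  # westward, replicating a light source to the East of the array
  d <- seq_len(n_colonies)
  p <- intensity_to_prob(p_ref, d = d, d_ref = 1, scheme = "linear",
                         d_far = n_colonies, p_min = p_min)
  colonies <- lapply(seq_len(n_colonies), function(k)
    colony_config(
      composition = data.frame(sensitivity = "all", fraction = 1,
                               taxis_sign = taxis_sign),
      sources = list(light_source(p[k], theta_deg = 0,
                                  wavelength = wavelength)),
      mode = "single", grid_dim = grid_dim))
  names(colonies) <- paste0("colony_", seq_len(n_colonies))
  list(colonies = colonies, meta = list(p = p, bearing_deg = 0,
                                        taxis_sign = taxis_sign))
}

preset_grid <- function(p_ref, grid_n, mode, grid_dim) {
  # colonies on integer grid coordinates (col = x east, row = y north);
  # sources one grid unit beyond the North and East edges, centred
  src_pos <- list(N = c((grid_n + 1) / 2, grid_n + 1),
                  E = c(grid_n + 1, (grid_n + 1) / 2))
  coords <- expand.grid(x = seq_len(grid_n), y = seq_len(grid_n))
  dists <- lapply(src_pos, function(sp)
    sqrt((coords$x - sp[1])^2 + (coords$y - sp[2])^2))
  colonies <- lapply(seq_len(nrow(coords)), function(k) {
    srcs <- lapply(names(src_pos), function(nm) {
      d <- dists[[nm]][k]
      light_source(intensity_to_prob(p_ref, d = d,
                                     d_ref = min(dists[[nm]])),
                   theta = source_bearing(unlist(coords[k, ]),
                                          src_pos[[nm]]))
    })
    colony_config(sources = srcs, mode = mode, grid_dim = grid_dim)
  })
  names(colonies) <- sprintf("colony_x%d_y%d", coords$x, coords$y)
  list(colonies = colonies,
       meta = list(coords = coords, src_pos = src_pos,
                   p1 = intensity_to_prob(p_ref, dists$N,
                                          d_ref = min(dists$N)),
                   p2 = intensity_to_prob(p_ref, dists$E,
                                          d_ref = min(dists$E))))
}

preset_pair <- function(p_ref, separation_deg, mode, grid_dim) {
  srcs <- list(light_source(p_ref, theta_deg = separation_deg),
               light_source(p_ref, theta_deg = -separation_deg))
  list(colonies = list(colony_1 = colony_config(sources = srcs, mode = mode,
                                                grid_dim = grid_dim)),
       meta = list(separation_deg = separation_deg, mode = mode))
}

preset_mixed <- function(p_ref, separation_deg, ratio, grid_dim) {
  ratio <- ratio / sum(ratio)
  srcs <- list(light_source(p_ref, theta_deg = separation_deg,
                            wavelength = "red"),
               light_source(p_ref, theta_deg = -separation_deg,
                            wavelength = "green"))
  comp <- data.frame(sensitivity = c("red", "green"),
                     fraction = as.numeric(ratio), taxis_sign = 1)
  list(colonies = list(colony_1 = colony_config(
    composition = comp, sources = srcs, mode = "stochastic_switching",
    grid_dim = grid_dim)),
       meta = list(separation_deg = separation_deg, ratio = ratio))
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("<experiment_preset> %s: %d colony(ies)\n", x$name,
              length(x$colonies)))
  invisible(x)
}

#' Run an experiment preset
#'
#' @param preset an [build_preset()] object.
#' @param seed master seed (default: the preset's `params$seed`).
#' @param record_stride,record_cells,n_steps as in [run_colony()].
#' @return A list of `"colony_run"`, one per colony.
#' @export
run_preset <- function(preset, seed = preset$params$seed,
                       record_stride = 100L, record_cells = NULL,
                       n_steps = preset$params$n_steps) {
  run_experiment(preset$colonies, preset$params, seed = seed,
                 record_stride = record_stride, record_cells = record_cells,
                 n_steps = n_steps)
}
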