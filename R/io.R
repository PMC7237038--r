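#' Write and read trajectory positions as CSV
#'
#' Serialises trajectory logs to a flat CSV with header `colony_id, step,
#' cell_id, x, y, sensitivity, taxis_sign`, one row per recorded cell
#' position; reading the file back reconstructs the logs exactly.
#'
#' @param runs a `"colony_run"`, a `"trajectory_log"`, or a list of either
#'   (one element per colony).
#' @param path CSV file path.
#' @return `write_positions` returns `path` invisibly; `read_positions` a
#'   named list of `"trajectory_log"` objects, one per `colony_id`.
#' @export
write_positions <- function(runs, path) {
  logs <- as_log_list(runs)
  rows <- lapply(seq_along(logs), function(k) {
    log <- logs[[k]]
    nr <- length(log$times)
    nc <- length(log$cell_ids)
    data.frame(colony_id = names(logs)[k],
               step = rep(log$times, times = nc),
               cell_id = rep(log$cell_ids, each = nr),
               x = as.numeric(log$positions[, , 1L]),
               y = as.numeric(log$positions[, , 2L]),
               sensitivity = rep(log$sensitivity, each = nr),
               taxis_sign = rep(log$taxis_sign, each = nr))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

as_log_list <- function(runs) {
  one <- function(x) if (inherits(x, "colony_run")) x$log else x
  if (inherits(runs, c("colony_run", "trajectory_log")))
    runs <- list(colony_1 = runs)
  logs <- lapply(runs, one)
  if (!all(vapply(logs, inherits, logical(1L), "trajectory_log")))
    stop("runs must be colony_run or trajectory_log objects", call. = FALSE)
  if (is.null(names(logs)) || any(names(logs) == ""))
    names(logs) <- paste0("colony_", seq_along(logs))
  logs
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("colony_id", "step", "cell_id", "x", "y", "sensitivity",
                "taxis_sign")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("positions file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(df[, c("step", "cell_id", "x", "y")]))
  if (length(bad))
    stop("malformed positions row at line ", bad[1L] + 1L, call. = FALSE)
  out <- lapply(split(df, df$colony_id), function(d) {
    times <- sort(unique(d$step))
    cells <- sort(unique(d$cell_id))
    nr <- length(times)
    nc <- length(cells)
    d <- d[order(match(d$cell_id, cells), match(d$step, times)), ]
    pos <- array(c(d$x, d$y), dim = c(nr, nc, 2L))
    first <- d[match(cells, d$cell_id), ]
    stride <- if (nr > 1L) {
      dt <- diff(times)
      as.integer(min(dt))
    } else 1L
    structure(list(times = times, positions = pos, cell_ids = cells,
                   record_stride = stride,
                   sensitivity = first$sensitivity,
                   taxis_sign = first$taxis_sign),
              class = "trajectory_log")
  })
  out[unique(df$colony_id)]
}

#' Write and read a run manifest
#'
#' A manifest is a JSON document that fully reproduces a run: the parameter
#' set, every colony configuration with its resolved sources, the master
#' seed and the recording stride. `run_manifest()` re-executes it.
#'
#' @param path manifest file path (JSON).
#' @param configs list of [colony_config()].
#' @param params a [taxis_params()].
#' @param seed master seed of the run.
#' @param record_stride recording stride of the run.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` a list
#'   with elements `configs`, `params`, `seed`, `record_stride`;
#'   `run_manifest` the list of `"colony_run"`.
#' @export
write_manifest <- function(path, configs, params, seed,
                           record_stride = 100L) {
  ser_src <- function(s) list(theta = s$theta, p = s$p,
                              wavelength = s$wavelength,
                              position = s$position)
  ser_cfg <- function(cc) list(
    centre = cc$centre, n_cells = cc$n_cells, density = cc$density,
    composition = as.list(cc$composition), sources = lapply(cc$sources,
                                                            ser_src),
    mode = cc$mode, grid_dim = cc$grid_dim,
    deposit_premove = cc$deposit_premove, reciprocal = cc$reciprocal)
  doc <- list(package = "cyanotaxis", params = unclass(params),
              colonies = lapply(configs, ser_cfg), seed = seed,
              record_stride = record_stride)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  de_src <- function(s) light_source(p = s$p, theta = s$theta,
                                     wavelength = s$wavelength,
                                     position = unlist(s$position))
  de_cfg <- function(cc) colony_config(
    centre = unlist(cc$centre), n_cells = cc$n_cells, density = cc$density,
    composition = as.data.frame(lapply(cc$composition, unlist)),
    sources = lapply(cc$sources, de_src), mode = cc$mode,
    grid_dim = unlist(cc$grid_dim),
    deposit_premove = isTRUE(cc$deposit_premove),
    reciprocal = isTRUE(cc$reciprocal))
  list(configs = lapply(doc$colonies, de_cfg),
       params = do.call(taxis_params, doc$params),
       seed = doc$seed, record_stride = doc$record_stride)
}

#' @rdname write_manifest
#' @export
run_manifest <- function(path) {
  man <- read_manifest(path)
  run_experiment(man$configs, man$params, seed = man$seed,
                 record_stride = man$record_stride)
}
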