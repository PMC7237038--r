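#' Light source
#'
#' A directional light stimulus, described by the bearing of the line joining
#' the colony centre to the source and by the probability `p` that a cell in
#' the colony takes a directed step toward it in one time unit. Intensity
#' enters the model only through `p`, which is uniform within a colony.
#'
#' Bearings follow the compass convention East = 0, North = 90 degrees,
#' measured anticlockwise from the horizontal; internally angles are radians
#' in `[0, 2*pi)`.
#'
#' @param p directed-move probability attributed to this source, in \[0, 1\].
#' @param theta_deg bearing in degrees (E = 0, N = 90). Exactly one of
#'   `theta_deg`, `theta` must be given unless `position` is supplied.
#' @param theta bearing in radians.
#' @param wavelength wavelength tag (`"red"`, `"green"`, `"UV"`, ...), matched
#'   against cell sensitivity tags.
#' @param position optional 2-D source position, used by distance-dependent
#'   intensity schemes and to derive the bearing from a colony centre.
#' @return An object of class `"light_source"`.
#' @examples
#' light_source(p = 0.05, theta_deg = 90)        # due North
#' light_source(p = 0.05, position = c(100, 0))  # bearing resolved per colony
#' @export
light_source <- function(p, theta_deg = NULL, theta = NULL,
                         wavelength = "red", position = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]", call. = FALSE)
  if (!is.null(theta_deg) && !is.null(theta))
    stop("give only one of theta_deg, theta", call. = FALSE)
  if (!is.null(theta_deg)) theta <- theta_deg * pi / 180
  if (is.null(theta) && is.null(position))
    stop("a light source needs a bearing (theta/theta_deg) or a position",
         call. = FALSE)
  src <- list(theta = if (!is.null(theta)) norm_angle(theta) else NULL,
              p = p, wavelength = wavelength, position = position)
  class(src) <- "light_source"
  src
}

#' @export
print.light_source <- function(x, ...) {
  bearing <- if (is.null(x$theta)) "(from position)" else
    sprintf("%.1f deg", x$theta * 180 / pi)
  cat(sprintf("<light_source> %s @ %s, p = %g\n", x$wavelength, bearing, x$p))
  invisible(x)
}

# wrap an angle into [0, 2*pi)
norm_angle <- function(theta) {
  out <- theta %% (2 * pi)
  # %% can return 2*pi for tiny negative inputs through rounding
  out[out >= 2 * pi] <- 0
  out
}

#' Bearing from a colony centre to a light source
#'
#' The angle that the line joining the colony centre to the source makes with
#' the horizontal (East = 0), anticlockwise, in `[0, 2*pi)`.
#'
#' @param centre,source_position 2-D coordinates.
#' @return Bearing in radians.
#' @examples
#' source_bearing(c(0, 0), c(0, 5))   # pi/2, due North
#' @export
source_bearing <- function(centre, source_position) {
  d <- source_position - centre
  if (all(d == 0))
    stop("source position coincides with the colony centre", call. = FALSE)
  norm_angle(atan2(d[2], d[1]))
}

#' Map light intensity at a distance to a directed-move probability
#'
#' Converts source distance to the per-step probability `p_k` of a directed
#' move. Two schemes are supported: `"inverse"`, where intensity (and hence
#' `p`) falls off as `1/d` from a reference value `p_ref` at distance `d_ref`;
#' and `"linear"`, where `p` interpolates linearly from `p_ref` at `d_ref`
#' down to `p_min` at `d_far` (clamped beyond). Results are clipped to
#' \[0, 1\].
#'
#' @param p_ref probability at the reference distance.
#' @param d distance(s) from colony centre to source; vectorised.
#' @param d_ref reference distance.
#' @param scheme `"inverse"` or `"linear"`.
#' @param d_far distance at which the linear scheme reaches `p_min`.
#' @param p_min probability floor of the linear scheme.
#' @return Probabilities, same length as `d`.
#' @examples
#' intensity_to_prob(0.05, d = 2, d_ref = 1)                   # 0.025
#' intensity_to_prob(0.05, d = 1:5, d_ref = 1, scheme = "linear",
#'                   d_far = 5, p_min = 0.01)                  # 0.05 .. 0.01
#' @export
intensity_to_prob <- function(p_ref, d, d_ref = 1,
                              scheme = c("inverse", "linear"),
                              d_far = NULL, p_min = 0.01) {
  scheme <- match.arg(scheme)
  if (any(d <= 0) || d_ref <= 0)
    stop("distances must be positive", call. = FALSE)
  if (p_ref < 0 || p_ref > 1)
    stop("p_ref must be in [0, 1]", call. = FALSE)
  p <- if (scheme == "inverse") {
    p_ref * d_ref / d
  } else {
    if (is.null(d_far)) stop("linear scheme needs d_far", call. = FALSE)
    frac <- (d - d_ref) / (d_far - d_ref)
    frac <- pmin(pmax(frac, 0), 1)
    p_ref + frac * (p_min - p_ref)
  }
  pmin(pmax(p, 0), 1)
}

#' Vector sum of light sources
#'
#' Each source `k` contributes `v_k = p_k (cos theta_k, sin theta_k)`; under
#' vector integration cells bias their motion along `sum(v_k)`, whose norm is
#' the resultant probability `p_vec` and whose direction is `theta_vec`. With
#' exactly cancelling sources `p_vec = 0` and the bearing is undefined
#' (returned as `NA`).
#'
#' @param sources list of [light_source()] objects (bearings must be resolved).
#' @return A list of class `"vector_sum"`: `p_vec`, `theta_vec`, and the
#'   `components` matrix (one `v_k` per row).
#' @examples
#' s <- list(light_source(0.05, theta_deg = 30),
#'           light_source(0.05, theta_deg = -30))
#' vector_sum(s)$p_vec   # 2 * 0.05 * cos(30 deg) = 0.0866
#' @export
vector_sum <- function(sources) {
  if (length(sources) == 0L)
    return(structure(list(p_vec = 0, theta_vec = NA_real_,
                          components = matrix(numeric(), 0L, 2L)),
                     class = "vector_sum"))
  comp <- t(vapply(sources, function(s) {
    if (is.null(s$theta))
      stop("source bearing unresolved; supply theta or resolve from position",
           call. = FALSE)
    s$p * c(cos(s$theta), sin(s$theta))
  }, numeric(2L)))
  v <- colSums(comp)
  p_vec <- sqrt(sum(v^2))
  # exact cancellation up to floating-point noise counts as cancellation
  if (p_vec < 1e-12 * max(sum(abs(comp)), 1)) p_vec <- 0
  theta_vec <- if (p_vec == 0) NA_real_ else norm_angle(atan2(v[2], v[1]))
  structure(list(p_vec = p_vec, theta_vec = theta_vec, components = comp),
            class = "vector_sum")
}

#' Sources visible to a cell
#'
#' Cells carry a wavelength-sensitivity tag and perceive only sources whose
#' wavelength matches it; the tag `"all"` matches every source. A cell whose
#' visible list is empty moves purely at random.
#'
#' @param sensitivity a cell's sensitivity tag (e.g. `"red"`, `"all"`).
#' @param sources list of [light_source()] objects.
#' @return The matching subset of `sources`.
#' @export
visible_sources <- function(sensitivity, sources) {
  if (identical(sensitivity, "all")) return(sources)
  Filter(function(s) identical(s$wavelength, sensitivity), sources)
}

# Per-step decision table for one cell class: cumulative branch probabilities
# and the (taxis-sign adjusted) heading of each directed branch.
#  - stochastic_switching / single: one branch per visible source, prob p_k.
#  - vector_integration: a single branch at theta_vec with prob p_vec
#    (no branch when p_vec == 0).
# Negative taxis (sign = -1) flips each branch heading by pi.
decision_table <- function(sources, mode, taxis_sign = 1) {
  mode <- match.arg(mode, c("single", "stochastic_switching",
                            "vector_integration"))
  if (!taxis_sign %in% c(-1, 1))
    stop("taxis_sign must be +1 or -1", call. = FALSE)
  if (length(sources) == 0L)
    return(list(cump = numeric(), theta = numeric()))
  if (mode == "vector_integration") {
    vs <- vector_sum(sources)
    if (vs$p_vec > 1)
      stop("resultant probability p_vec exceeds 1", call. = FALSE)
    if (vs$p_vec == 0)
      return(list(cump = numeric(), theta = numeric()))
    p <- vs$p_vec
    th <- vs$theta_vec
  } else {
    p <- vapply(sources, `[[`, numeric(1L), "p")
    if (sum(p) > 1)
      stop("source probabilities sum to more than 1", call. = FALSE)
    th <- vapply(sources, function(s) {
      if (is.null(s$theta)) stop("source bearing unresolved", call. = FALSE)
      s$theta
    }, numeric(1L))
  }
  if (taxis_sign == -1) th <- norm_angle(th - pi)
  list(cump = cumsum(p), theta = norm_angle(th))
}

#' Draw per-step heading decisions
#'
#' Implements the per-step heading rule. Under `"stochastic_switching"` a cell
#' commits to source `k` (heading `theta_k`) with probability `p_k`, otherwise
#' it picks a uniform random heading on `[0, 2*pi)`. Under
#' `"vector_integration"` it heads along the vector-sum bearing `theta_vec`
#' with probability `p_vec`, otherwise uniformly at random. Negative
#' phototaxis (`taxis_sign = -1`) replaces every directed heading `theta` by
#' `theta - pi`. Cells that see no source (after the `sensitivity` filter)
#' always draw uniformly.
#'
#' Each decision consumes exactly two uniform draws (branch, then angle), in
#' that order — the same order as the simulation core, so heading statistics
#' produced here are reproducible against full runs.
#'
#' `decide_heading()` draws a single decision; `draw_headings()` draws `n`
#' independent decisions efficiently.
#'
#' @param sources list of [light_source()] with resolved bearings.
#' @param mode `"single"`, `"stochastic_switching"` or `"vector_integration"`.
#' @param taxis_sign `+1` (toward light) or `-1` (away).
#' @param sensitivity the cell's wavelength-sensitivity tag.
#' @param n number of decisions to draw.
#' @param seed optional integer seed applied via [set.seed()] before drawing.
#' @param detail if `TRUE`, return a data frame with the branch taken
#'   (`0` = random, `k` = directed toward the `k`-th branch of the decision
#'   table) alongside each heading.
#' @return `decide_heading`: a heading in radians with attribute `"branch"`.
#'   `draw_headings`: a numeric vector of headings, or a data frame
#'   (`heading`, `branch`) when `detail = TRUE`.
#' @examples
#' s <- list(light_source(0.05, theta_deg = 90),
#'           light_source(0.05, theta_deg = -90))
#' h <- draw_headings(1000, s, mode = "stochastic_switching", seed = 1,
#'                    detail = TRUE)
#' mean(h$branch == 1)   # about 0.05
#' @export
decide_heading <- function(sources, mode = "single", taxis_sign = 1,
                           sensitivity = "all") {
  tab <- decision_table(visible_sources(sensitivity, sources), mode,
                        taxis_sign)
  u1 <- stats::runif(1L)
  u2 <- stats::runif(1L)
  k <- branch_from_u(u1, tab$cump)
  heading <- if (k > 0L) tab$theta[k] else 2 * pi * u2
  structure(heading, branch = k)
}

#' @rdname decide_heading
#' @export
draw_headings <- function(n, sources, mode = "single", taxis_sign = 1,
                          sensitivity = "all", seed = NULL, detail = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  tab <- decision_table(visible_sources(sensitivity, sources), mode,
                        taxis_sign)
  u <- matrix(stats::runif(2L * n), nrow = 2L)  # column = (branch, angle)
  k <- branch_from_u(u[1L, ], tab$cump)
  heading <- 2 * pi * u[2L, ]
  if (length(tab$cump)) heading[k > 0L] <- tab$theta[k[k > 0L]]
  if (detail) data.frame(heading = heading, branch = k) else heading
}

# branch index for uniform draw u: k when cump[k-1] <= u < cump[k]
# (cump[0] = 0), 0 (random branch) when u >= cump[K]
branch_from_u <- function(u, cump) {
  if (length(cump) == 0L) return(integer(length(u)))
  k <- findInterval(u, c(0, cump))
  k[k > length(cump)] <- 0L
  as.integer(k)
}
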