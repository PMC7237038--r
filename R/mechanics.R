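#' Propulsion force from a chosen heading
#'
#' The decision of a cell to move along heading `theta` enters the overdamped
#' equation of motion as a force `G = f0 (cos theta, sin theta)` of fixed
#' magnitude `f0`.
#'
#' @param theta heading(s), radians; vectorised.
#' @param f0 propulsion magnitude.
#' @return An `n x 2` matrix of force vectors (one row per heading).
#' @export
propulsion_force <- function(theta, f0 = 1) {
  if (f0 < 0) stop("f0 must be >= 0", call. = FALSE)
  cbind(f0 * cos(theta), f0 * sin(theta))
}

#' Pili force kernel
#'
#' Magnitude of the force a pilus exerts between cells at centre-to-centre
#' distance `D`:
#' \deqn{K(D) = (1 + k_1(\tanh(k_2(D - 2R)) - 1))/m}
#' The kernel is sigmoidal: repulsive (negative) below contact `D = 2R`
#' (penalising overlap through a soft core), exactly zero at contact when
#' `k1 = 1`, and saturating to the attractive plateau `1/m` at long range.
#'
#' @param D distance(s) between cell centres; vectorised.
#' @param params a [taxis_params()] object (uses `radius`, `k1`, `k2`, `m`).
#' @return Force magnitudes; positive pulls the target toward the puller.
#' @examples
#' p <- taxis_params()
#' pair_force_magnitude(2, p)    # 0 at contact
#' pair_force_magnitude(1, p)    # < 0: soft-core repulsion
#' @export
pair_force_magnitude <- function(D, params = taxis_params()) {
  if (any(D <= 0)) stop("distances must be positive", call. = FALSE)
  (1 + params$k1 * (tanh(params$k2 * (D - 2 * params$radius)) - 1)) / params$m
}

#' Sample pili attachments
#'
#' Each cell `j` attaches its pili to targets drawn uniformly without
#' replacement from the neighbours within reach `ell` of its centre
#' (centre-to-centre, inclusive). When a cell has at most `m` neighbours it
#' attaches to all of them; otherwise to `m` of them. Attachments are redrawn
#' afresh every step.
#'
#' The neighbour search is spatially binned (bin width `ell`) and exact: it
#' returns the same neighbour sets as a brute-force all-pairs scan, in
#' ascending index order — the order in which selection draws are consumed.
#'
#' @param positions `N x 2` matrix of cell centres.
#' @param params a [taxis_params()] object (uses `ell`, `m`).
#' @param seed optional seed applied via [set.seed()] before sampling.
#' @return A data frame with one row per attachment: `puller`, `target`
#'   (1-based cell indices), `distance`, and `bearing` (angle of the vector
#'   from target to puller, radians).
#' @export
sample_attachments <- function(positions, params = taxis_params(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  positions <- as_positions(positions)
  res <- sample_attachments_cpp(positions, params$ell, params$m)
  data.frame(puller = res$puller, target = res$target,
             distance = res$distance, bearing = res$bearing)
}

#' Exact neighbour lists within pilus reach
#'
#' For each cell, the indices of all other cells within centre-to-centre
#' distance `ell` (inclusive), ascending. Computed with spatial binning; the
#' result is exact.
#'
#' @inheritParams sample_attachments
#' @param ell reach.
#' @return A list of integer vectors, one per cell.
#' @export
neighbour_lists <- function(positions, ell) {
  positions <- as_positions(positions)
  neighbour_lists_cpp(positions, ell)
}

#' Accumulate pili forces on target cells
#'
#' Sums the pili force contributions over a set of attachments. An attachment
#' of puller `j` on target `i` adds `K(D_ji) (cos theta_ji, sin theta_ji)` to
#' the total force on `i`, where `theta_ji` is the bearing from `i` to `j`;
#' positive `K` therefore pulls the target toward the puller and negative `K`
#' (short range) pushes it away. By default no reaction force acts on the
#' puller; set `reciprocal = TRUE` to apply the opposite force to `j` as well.
#'
#' @param attachments data frame as returned by [sample_attachments()].
#' @param positions `N x 2` matrix of cell centres.
#' @param params a [taxis_params()] object.
#' @param reciprocal apply Newtonian reaction forces to pullers.
#' @return An `N x 2` matrix of net pili forces `F_i`.
#' @export
accumulate_forces <- function(attachments, positions,
                              params = taxis_params(), reciprocal = FALSE) {
  positions <- as_positions(positions)
  n <- nrow(positions)
  F <- matrix(0, n, 2L)
  if (NROW(attachments) == 0L) return(F)
  dx <- positions[attachments$puller, 1L] - positions[attachments$target, 1L]
  dy <- positions[attachments$puller, 2L] - positions[attachments$target, 2L]
  D <- sqrt(dx^2 + dy^2)
  if (any(D == 0))
    stop("degenerate geometry: coincident puller and target", call. = FALSE)
  K <- pair_force_magnitude(D, params)
  fx <- K * dx / D
  fy <- K * dy / D
  tgt <- attachments$target
  F[, 1L] <- F[, 1L] + as.numeric(rowsum_at(fx, tgt, n))
  F[, 2L] <- F[, 2L] + as.numeric(rowsum_at(fy, tgt, n))
  if (reciprocal) {
    pul <- attachments$puller
    F[, 1L] <- F[, 1L] - as.numeric(rowsum_at(fx, pul, n))
    F[, 2L] <- F[, 2L] - as.numeric(rowsum_at(fy, pul, n))
  }
  F
}

# sum of x grouped by 1-based index into a length-n vector
rowsum_at <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

as_positions <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || !is.numeric(positions))
    stop("positions must be an N x 2 numeric matrix", call. = FALSE)
  storage.mode(positions) <- "double"
  positions
}
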