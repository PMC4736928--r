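# Trajectory statistics: three-point instantaneous speed, turning angles,
# freezing filter, occupancy grids and pairwise distances. Group-level
# statistics only are meaningful for groups (tracking identity switches
# make per-individual measures unreliable in the experimental protocol this
# mirrors); speed and turning series are intended for single-agent tracks.

# positions of one agent, ordered by time, as a matrix
.track_matrix <- function(trajs, id) {
  tr <- trajs[trajs$agent_id == id, , drop = FALSE]
  tr <- tr[order(tr$time_s), , drop = FALSE]
  cbind(tr$x_m, tr$y_m)
}

#' Three-point instantaneous speed
#'
#' v(t) = |P(t+1) - P(t-1)| / (2 dt), the central-difference speed over one
#' recording interval on each side; the two endpoint samples are omitted.
#'
#' @param track an n x 2 matrix of positions (metres) on a uniform time
#'   base, or a single-agent [trajectory_set()].
#' @param dt_record recording interval in seconds (taken from the
#'   trajectory attribute when `track` is a trajectory set).
#' @return numeric vector of n - 2 speeds in m/s (empty if n < 3).
#' @export
instantaneous_speed <- function(track, dt_record = NULL) {
  if (inherits(track, "trajectory_set")) {
    if (is.null(dt_record)) dt_record <- attr(track, "interval")
    track <- .track_matrix(track, track$agent_id[1])
  }
  stopifnot(!is.null(dt_record), dt_record > 0)
  n <- nrow(track)
  if (n < 3) return(numeric(0))
  dx <- track[3:n, 1] - track[1:(n - 2), 1]
  dy <- track[3:n, 2] - track[1:(n - 2), 2]
  sqrt(dx^2 + dy^2) / (2 * dt_record)
}

#' Turning angles between successive displacement vectors
#'
#' The signed angle in \[-pi, pi) between (P(t) - P(t-1)) and
#' (P(t+1) - P(t)); positive turns are leftward (counter-clockwise).
#' Samples involving a zero-length displacement are skipped.
#'
#' @param track an n x 2 position matrix or a single-agent
#'   [trajectory_set()].
#' @return numeric vector of signed turning angles in radians.
#' @export
turning_angles <- function(track) {
  if (inherits(track, "trajectory_set")) {
    track <- .track_matrix(track, track$agent_id[1])
  }
  n <- nrow(track)
  if (n < 3) return(numeric(0))
  vx <- diff(track[, 1])
  vy <- diff(track[, 2])
  len <- sqrt(vx^2 + vy^2)
  m <- n - 1
  ok <- len[1:(m - 1)] > 0 & len[2:m] > 0
  # angle of v2 relative to v1 via atan2 of cross and dot products
  cross <- vx[1:(m - 1)] * vy[2:m] - vy[1:(m - 1)] * vx[2:m]
  dot <- vx[1:(m - 1)] * vx[2:m] + vy[1:(m - 1)] * vy[2:m]
  wrap_angle(atan2(cross, dot)[ok])
}

#' Remove freezing episodes from a speed series
#'
#' Freezing (immobility) is excluded from speed statistics: only samples
#' strictly greater than 1 mm/s are retained.
#'
#' @param speeds numeric vector of speeds in m/s.
#' @param threshold freezing threshold in m/s.
#' @return the speeds above the threshold.
#' @export
filter_freezing <- function(speeds, threshold = 0.001) {
  speeds[speeds > threshold]
}

#' Regime-conditional speed samples
#'
#' Splits three-point instantaneous speed samples by spot regime. Because
#' the estimator spans three consecutive positions, a sample is attributed
#' to a regime only when its whole stencil (t - 1, t, t + 1) lies in that
#' regime; samples straddling a spot boundary belong to neither regime and
#' are dropped, so each conditional mean reflects a single speed
#' distribution.
#'
#' @param trajs a [trajectory_set()].
#' @param spots list of [spot()]s.
#' @param freezing_filter drop samples at or below 1 mm/s (default `TRUE`).
#' @return list with numeric vectors `outside` and `under` (m/s).
#' @export
speeds_by_regime <- function(trajs, spots, freezing_filter = TRUE) {
  outside <- list(); under <- list()
  dt <- attr(trajs, "interval")
  for (id in unique(trajs$agent_id)) {
    track <- .track_matrix(trajs, id)
    n <- nrow(track)
    if (n < 3) next
    v <- instantaneous_speed(track, dt)
    flag <- vapply(seq_len(n), function(k) {
      under_spot(track[k, ], spots)$under
    }, logical(1))
    pure_under <- flag[1:(n - 2)] & flag[2:(n - 1)] & flag[3:n]
    pure_out <- !flag[1:(n - 2)] & !flag[2:(n - 1)] & !flag[3:n]
    outside[[length(outside) + 1L]] <- v[pure_out]
    under[[length(under) + 1L]] <- v[pure_under]
  }
  out <- list(outside = unlist(outside), under = unlist(under))
  if (freezing_filter) out <- lapply(out, filter_freezing)
  out
}

#' Occupancy grid (probability of presence)
#'
#' Counts recorded positions per square cell and normalizes to total 1.
#'
#' @param trajs a [trajectory_set()].
#' @param bin cell side in metres; must divide the arena side (default
#'   0.05 m, a 24 x 24 grid over the 1.2 m tank).
#' @return a matrix of cell probabilities; rows index x cells, columns y
#'   cells, cell \[1, 1\] at the arena origin.
#' @export
occupancy_grid <- function(trajs, bin = 0.05) {
  side <- attr(trajs, "arena_side")
  ncell <- side / bin
  if (abs(ncell - round(ncell)) > 1e-9) {
    stop("occupancy_grid: bin must divide the arena side")
  }
  ncell <- as.integer(round(ncell))
  if (any(trajs$x_m < 0 | trajs$x_m > side | trajs$y_m < 0 | trajs$y_m > side)) {
    stop("occupancy_grid: positions outside the arena")
  }
  ix <- pmin(floor(trajs$x_m / bin) + 1L, ncell)
  iy <- pmin(floor(trajs$y_m / bin) + 1L, ncell)
  g <- matrix(0, ncell, ncell)
  for (k in seq_along(ix)) g[ix[k], iy[k]] <- g[ix[k], iy[k]] + 1
  g / sum(g)
}

#' Pairwise inter-agent distances per recorded frame
#'
#' All n (n - 1) / 2 Euclidean distances between agents at each recorded
#' time; their pooled distribution measures group cohesion.
#'
#' @param trajs a [trajectory_set()] with at least two agents.
#' @return numeric vector of distances in metres, pooled over frames.
#' @export
pairwise_distances <- function(trajs) {
  ids <- unique(trajs$agent_id)
  if (length(ids) < 2) stop("pairwise_distances: needs at least 2 agents")
  times <- unique(trajs$time_s)
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    fr <- trajs[trajs$time_s == times[k], , drop = FALSE]
    out[[k]] <- as.numeric(stats::dist(cbind(fr$x_m, fr$y_m)))
  }
  unlist(out)
}
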