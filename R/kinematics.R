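# Arena geometry, wall interaction, speed regimes, and the discrete-time
# position/heading update.

#' Square arena
#'
#' Axis-aligned square tank with its origin at a corner; coordinates lie in
#' \[0, side\]^2. Walls are identified as "N" (y = side), "E" (x = side),
#' "S" (y = 0) and "W" (x = 0).
#'
#' @param side side length in metres (default 1.20, the experimental tank).
#' @return an object of class `arena`.
#' @export
arena <- function(side = 1.2) {
  stopifnot(.is_number(side), side > 0)
  structure(list(side = side), class = "arena")
}

#' Floating spot of interest
#'
#' A disc floating above the swimming plane, acting as a shaded attractive
#' area.
#'
#' @param x,y centre coordinates in metres.
#' @param radius disc radius in metres (default 0.1).
#' @param height height above the swimming plane in metres (default 0.05).
#' @return an object of class `spot`.
#' @export
spot <- function(x, y, radius = 0.1, height = 0.05) {
  stopifnot(radius > 0, height > 0)
  structure(list(centre = c(x, y), radius = radius, height = height),
            class = "spot")
}

#' Default two-spot layout
#'
#' Two spots on the main diagonal of the arena, centres 0.70 m apart,
#' symmetric about the arena centre.
#'
#' @param a an [arena()].
#' @param spacing centre-to-centre distance in metres.
#' @return list of two [spot()]s.
#' @export
default_spots <- function(a = arena(), spacing = 0.70) {
  half <- spacing / (2 * sqrt(2))
  c0 <- a$side / 2
  list(spot(c0 - half, c0 - half), spot(c0 + half, c0 + half))
}

#' Agent state
#'
#' @param x,y head position in metres.
#' @param heading world-frame heading in radians (wrapped to \[-pi, pi)).
#' @param speed current linear speed in m/s.
#' @return an object of class `agent_state`.
#' @export
agent_state <- function(x, y, heading = 0, speed = 0) {
  stopifnot(speed >= 0)
  structure(list(position = c(x, y), heading = wrap_angle(heading),
                 speed = speed), class = "agent_state")
}

#' Distance to the nearest wall
#'
#' @param position `(x, y)` inside the arena.
#' @param a an [arena()].
#' @return list with `d` (metres) and `wall` (one of "N", "E", "S", "W");
#'   ties break deterministically in the order N, E, S, W.
#' @export
distance_to_nearest_wall <- function(position, a = arena()) {
  x <- position[1]; y <- position[2]
  if (x < 0 || x > a$side || y < 0 || y > a$side) {
    stop("distance_to_nearest_wall: position outside the arena")
  }
  d <- c(N = a$side - y, E = a$side - x, S = y, W = x)
  k <- which.min(d)  # first minimum in N, E, S, W order
  list(d = unname(d[k]), wall = names(d)[k])
}

#' Body-frame directions along a wall
#'
#' The two world directions parallel to the given wall, converted into the
#' agent's body frame.
#'
#' @param wall wall id ("N", "E", "S" or "W").
#' @param heading agent world-frame heading in radians.
#' @return numeric `(mu_w1, mu_w2)` body-frame directions.
#' @export
wall_following_directions <- function(wall, heading) {
  wall <- match.arg(wall, c("N", "E", "S", "W"))
  world <- if (wall %in% c("N", "S")) c(0, pi) else c(pi / 2, -pi / 2)
  wrap_angle(world - heading)
}

#' Is a position under a floating spot?
#'
#' @param position `(x, y)` in metres.
#' @param spots list of [spot()]s.
#' @return list with `under` (logical) and `spot` (index of the covering
#'   spot, or `NA`); the disc boundary is inclusive.
#' @export
under_spot <- function(position, spots) {
  for (j in seq_along(spots)) {
    dx <- position[1] - spots[[j]]$centre[1]
    dy <- position[2] - spots[[j]]$centre[2]
    # inclusive boundary, robust to rounding of the radius comparison
    if (sqrt(dx^2 + dy^2) <= spots[[j]]$radius + 1e-12) {
      return(list(under = TRUE, spot = j))
    }
  }
  list(under = FALSE, spot = NA_integer_)
}

#' Speed model
#'
#' Per-regime instantaneous speed distributions. Each regime is a normal
#' distribution truncated at zero with the given mean and standard
#' deviation; the defaults reproduce the measured regimes (homogeneous
#' tank 0.07 +/- 0.03 m/s; with spots present 0.09 +/- 0.06 m/s outside and
#' 0.03 +/- 0.02 m/s under a spot). Alternatively a regime may carry an
#' empirical sample pool (a numeric vector of non-negative speeds) that is
#' resampled with replacement.
#'
#' @param homogeneous,outside_spot,under_spot either `c(mean, sd)` in m/s
#'   or a numeric pool of observed speeds (length > 2).
#' @return an object of class `speed_model`.
#' @export
speed_model <- function(homogeneous = c(0.07, 0.03),
                        outside_spot = c(0.09, 0.06),
                        under_spot = c(0.03, 0.02)) {
  regimes <- list(homogeneous = homogeneous, outside_spot = outside_spot,
                  under_spot = under_spot)
  for (nm in names(regimes)) {
    r <- regimes[[nm]]
    if (!is.numeric(r) || any(r < 0) || (length(r) == 2 && any(r <= 0))) {
      stop(sprintf("speed_model: regime '%s' must be c(mean, sd) > 0 or a non-negative pool", nm))
    }
  }
  structure(regimes, class = "speed_model")
}

#' Draw an instantaneous speed
#'
#' Draws are serially independent; truncated-normal regimes are sampled by
#' inverse transform on the conditional-on-positive CDF so every draw is
#' non-negative.
#'
#' @param regime regime name ("homogeneous", "outside_spot" or
#'   "under_spot").
#' @param model a [speed_model()].
#' @param n number of draws.
#' @return `n` non-negative speeds in m/s.
#' @export
sample_speed <- function(regime, model = speed_model(), n = 1) {
  r <- model[[regime]]
  if (is.null(r)) stop(sprintf("sample_speed: unknown regime '%s'", regime))
  if (length(r) == 2) {
    p0 <- stats::pnorm(0, r[1], r[2])
    stats::qnorm(p0 + stats::runif(n) * (1 - p0), r[1], r[2])
  } else {
    r[sample.int(length(r), n, replace = TRUE)]
  }
}

#' Advance an agent by one time step
#'
#' The new heading is the old heading plus the sampled body-frame turn; the
#' agent then moves `v * dt` along the new heading. If the displacement
#' segment would exit the arena it is truncated so the agent stops 1e-4 m
#' inside the boundary, keeping the sampled heading (so the wall-following
#' density takes over at the next decision).
#'
#' @param state an [agent_state()].
#' @param theta_rel sampled body-frame turn in radians.
#' @param v speed for this step in m/s.
#' @param dt time step in seconds.
#' @param a an [arena()].
#' @return the updated [agent_state()].
#' @export
step_agent <- function(state, theta_rel, v, dt, a = arena()) {
  heading <- wrap_angle(state$heading + theta_rel)
  pos <- .advance_position(state$position, heading, v * dt, a$side)
  agent_state(pos[1], pos[2], heading, v)
}

# distance along the current heading to the first wall impact, and the
# wall that would be hit; `exclude` drops one wall from consideration
# (used when an agent hugs a wall, whose shallow impacts are irrelevant)
.wall_ahead <- function(pos, heading, side, exclude = NA_character_) {
  ux <- cos(heading); uy <- sin(heading)
  d <- c(E = if (ux > 0) (side - pos[1]) / ux else Inf,
         W = if (ux < 0) -pos[1] / ux else Inf,
         N = if (uy > 0) (side - pos[2]) / uy else Inf,
         S = if (uy < 0) -pos[2] / uy else Inf)
  if (!is.na(exclude)) d[exclude] <- Inf
  k <- which.min(d)
  list(dist = unname(d[k]), wall = names(d)[k])
}

# displacement of length len along heading with specular reflection at the
# walls (billiard boundary); preserves path length. Returns list(pos,
# heading) with the post-reflection heading.
.advance_reflecting <- function(pos, heading, len, side, eps = 1e-4) {
  ux <- cos(heading); uy <- sin(heading)
  x <- pos[1]; y <- pos[2]
  for (iter in 1:8) {
    if (len <= 0) break
    tx <- if (ux > 0) (side - eps - x) / ux else if (ux < 0) (eps - x) / ux else Inf
    ty <- if (uy > 0) (side - eps - y) / uy else if (uy < 0) (eps - y) / uy else Inf
    tc <- min(tx, ty)
    if (tc >= len) {
      x <- x + len * ux; y <- y + len * uy
      len <- 0
    } else {
      tc <- max(tc, 0)
      x <- x + tc * ux; y <- y + tc * uy
      len <- len - tc
      if (tx <= ty) ux <- -ux else uy <- -uy
    }
  }
  list(pos = c(x, y), heading = atan2(uy, ux))
}

# displacement of length len along heading, truncated eps inside the walls
.advance_position <- function(pos, heading, len, side, eps = 1e-4) {
  if (len <= 0) return(pos)
  ux <- cos(heading); uy <- sin(heading)
  smax <- 1
  if (ux > 0) smax <- min(smax, (side - eps - pos[1]) / (ux * len))
  if (ux < 0) smax <- min(smax, (pos[1] - eps) / (-ux * len))
  if (uy > 0) smax <- min(smax, (side - eps - pos[2]) / (uy * len))
  if (uy < 0) smax <- min(smax, (pos[2] - eps) / (-uy * len))
  smax <- max(smax, 0)
  c(pos[1] + smax * len * ux, pos[2] + smax * len * uy)
}
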