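# Simulation engine: perception -> decision -> sampling -> kinematics for
# all agents over time, with seeded reproducibility. Updates are
# synchronous: every agent perceives the time-t states of the others, then
# all positions advance together.

#' Run configuration
#'
#' @param arena an [arena()].
#' @param spots list of [spot()]s (possibly empty).
#' @param n_agents number of agents (>= 1).
#' @param duration simulated time in seconds.
#' @param dt update interval in seconds (default 1/3 s, so a 1 h run takes
#'   exactly 10 800 updates).
#' @param params a [behaviour_params()].
#' @param speeds a [speed_model()].
#' @param seed RNG seed (integer); drawn at random and recorded if omitted.
#' @param record_interval recording interval in seconds (multiple of `dt`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(arena = zebravis::arena(), spots = list(),
                       n_agents = 1, duration = 3600, dt = 1 / 3,
                       params = behaviour_params(), speeds = speed_model(),
                       seed = NULL, record_interval = 1) {
  stopifnot(inherits(arena, "arena"), inherits(params, "behaviour_params"),
            inherits(speeds, "speed_model"), n_agents >= 1, duration > 0,
            dt > 0, record_interval > 0)
  for (s in spots) {
    stopifnot(inherits(s, "spot"))
    if (any(s$centre - s$radius < 0) || any(s$centre + s$radius > arena$side)) {
      stop("run_config: spot disc must lie fully inside the arena")
    }
  }
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("run_config: duration must be an integer multiple of dt")
  }
  rec_every <- record_interval / dt
  if (abs(rec_every - round(rec_every)) > 1e-9) {
    stop("run_config: record_interval must be an integer multiple of dt")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  structure(list(arena = arena, spots = spots, n_agents = n_agents,
                 duration = duration, dt = dt, params = params,
                 speeds = speeds, seed = as.integer(seed),
                 record_interval = record_interval,
                 n_steps = as.integer(round(n_steps)),
                 record_every = as.integer(round(rec_every))),
            class = "run_config")
}

#' Trajectory set
#'
#' Per-agent time series of positions on a shared uniform time base.
#'
#' @param data a data.frame with columns `time_s`, `agent_id`, `x_m`, `y_m`.
#' @param interval sampling interval in seconds.
#' @param arena_side arena side length in metres.
#' @return an object of class `trajectory_set` (a data.frame).
#' @export
trajectory_set <- function(data, interval, arena_side = 1.2) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "agent_id", "x_m", "y_m") %in% names(data)))
  if (nrow(data) > 0) {
    if (any(data$x_m < 0 | data$x_m > arena_side |
            data$y_m < 0 | data$y_m > arena_side)) {
      stop("trajectory_set: positions outside the declared arena")
    }
    for (id in unique(data$agent_id)) {
      tt <- data$time_s[data$agent_id == id]
      if (is.unsorted(tt, strictly = TRUE)) {
        stop("trajectory_set: time must be strictly increasing within agent")
      }
    }
  }
  structure(data, interval = interval, arena_side = arena_side,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d agents, %d frames, interval %.3g s, arena %.2f m\n",
              length(unique(x$agent_id)),
              length(unique(x$time_s)),
              attr(x, "interval"), attr(x, "arena_side")))
  invisible(x)
}

#' Initialize agent states
#'
#' Mirrors the experimental release protocol: agents start inside a central
#' cylindrical arena of 0.20 m diameter, with positions uniform over that
#' disc, headings uniform over \[-pi, pi), and initial speeds drawn from
#' the regime applicable at the initial position.
#'
#' @param config a [run_config()]. Uses the current RNG state (seed the
#'   session, or call via [simulate_school()] which seeds from the config).
#' @return list of [agent_state()]s.
#' @export
initialize_agents <- function(config) {
  n <- config$n_agents
  if (n > 1e4) stop("initialize_agents: too many agents for the release disc")
  c0 <- config$arena$side / 2
  out <- vector("list", n)
  has_spots <- length(config$spots) > 0
  for (i in seq_len(n)) {
    r <- 0.10 * sqrt(stats::runif(1))
    phi <- stats::runif(1, -pi, pi)
    x <- c0 + r * cos(phi)
    y <- c0 + r * sin(phi)
    heading <- stats::runif(1, -pi, pi)
    regime <- if (!has_spots) "homogeneous" else if (under_spot(c(x, y), config$spots)$under) "under_spot" else "outside_spot"
    v <- sample_speed(regime, config$speeds, 1)
    out[[i]] <- agent_state(x, y, heading, v)
  }
  out
}

# fish percept of target (precomputed vertices/centroid) from a focal
# agent; returns c(bearing, solid_angle) or NULL when out of view or
# degenerate (overlapping agents are allowed, so coincident geometry is
# skipped rather than raised).
.fish_percept <- function(fpos, fheading, verts, centroid, half_fov) {
  dx <- centroid[1] - fpos[1]
  dy <- centroid[2] - fpos[2]
  if (abs(dx) + abs(dy) < 1e-9) return(NULL)
  fx <- cos(fheading); fy <- sin(fheading)
  bx <- dx * fx + dy * fy
  by <- -dx * fy + dy * fx
  rh <- sqrt(bx^2 + by^2)
  bearing <- atan2(by, bx)
  if (abs(bearing) > half_fov) return(NULL)
  pr <- .project_fast(verts, fpos[1], fpos[2], fheading)
  az0 <- atan2(mean(sin(pr$az)), mean(cos(pr$az)))
  omega <- .extremal_omega_fast(pr$az, pr$el, az0)
  if (!is.finite(omega) || omega <= 0) return(NULL)
  c(bearing, omega)
}

# spot percept from a focal agent: bearing of the spot centre and the
# extremal-quad solid angle of the disc rim
.spot_percept <- function(fpos, fheading, s, half_fov) {
  dx <- s$centre[1] - fpos[1]
  dy <- s$centre[2] - fpos[2]
  fx <- cos(fheading); fy <- sin(fheading)
  bx <- dx * fx + dy * fy
  by <- -dx * fy + dy * fx
  bearing <- atan2(by, bx)
  if (abs(bearing) > half_fov) return(NULL)
  dh <- sqrt(dx^2 + dy^2)
  if (dh < 1e-12) { ux <- fx; uy <- fy } else { ux <- dx / dh; uy <- dy / dh }
  R <- s$radius
  rim <- cbind(s$centre[1] + R * c(-ux, -uy, ux, uy),
               s$centre[2] + R * c(-uy, ux, uy, -ux),
               s$height)
  pr <- .project_fast(rim, fpos[1], fpos[2], fheading)
  omega <- .quad_omega_fast(pr$az, pr$el)
  if (!is.finite(omega) || omega <= 0) return(NULL)
  c(bearing, omega)
}

#' Simulate a school of agents
#'
#' Runs the full perception -> decision -> sampling -> kinematics loop for
#' `duration / dt` synchronous updates. Per update and per agent (in id
#' order) one speed draw and one direction draw are consumed from a single
#' seeded RNG stream, so identical configurations give bit-identical
#' trajectories.
#'
#' @param config a [run_config()].
#' @return a [trajectory_set()] recorded every `record_interval` seconds
#'   (including the initial state); the attribute `n_updates` carries the
#'   number of executed updates.
#' @export
simulate_school <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  n <- config$n_agents
  params <- config$params
  spots <- config$spots
  a <- config$arena
  has_spots <- length(spots) > 0
  mixed <- has_spots && n > 1
  half_fov <- params$fov / 2
  grid <- direction_grid()
  ng <- length(grid)
  h <- grid[2] - grid[1]
  base_far <- von_mises_pdf(grid, 0, params$kappa0)
  norm_f <- 2 * pi * bessel_i0(params$kappaF)
  norm_s <- 2 * pi * bessel_i0(params$kappaS)

  init <- initialize_agents(config)
  st <- t(vapply(init, function(s) c(s$position, s$heading, s$speed),
                 numeric(4)))

  n_frames <- config$n_steps %/% config$record_every + 1L
  rec <- matrix(NA_real_, n_frames * n, 4)
  frame <- 1L
  record <- function(step) {
    t_s <- step * config$dt
    idx <- ((frame - 1L) * n + 1L):(frame * n)
    rec[idx, ] <<- cbind(t_s, seq_len(n), st[, 1], st[, 2])
    frame <<- frame + 1L
  }
  record(0L)

  spot_pts <- if (has_spots) {
    lapply(spots, function(s) c(s$centre, s$height))
  } else list()

  for (step in seq_len(config$n_steps)) {
    if (n > 1) {
      verts <- lapply(seq_len(n), function(i) {
        body_vertices(st[i, 1:2], st[i, 3], params$body)
      })
      cents <- lapply(verts, colMeans)
    }
    new_st <- st
    for (i in seq_len(n)) {
      fpos <- st[i, 1:2]
      fheading <- st[i, 3]
      wall <- distance_to_nearest_wall(fpos, a)

      # baseline / wall-following component
      if (wall$d >= params$dW) {
        dens <- base_far
      } else {
        mw <- wall_following_directions(wall$wall, fheading)
        dens <- 0.5 * von_mises_pdf(grid, mw[1], params$kappaW) +
          0.5 * von_mises_pdf(grid, mw[2], params$kappaW)
      }

      # fish component
      ATf <- 0
      if (n > 1) {
        mus <- numeric(0); As <- numeric(0)
        for (j in seq_len(n)) {
          if (j == i) next
          p <- .fish_percept(fpos, fheading, verts[[j]], cents[[j]], half_fov)
          if (!is.null(p)) { mus <- c(mus, p[1]); As <- c(As, p[2]) }
        }
        if (length(As) > 0) {
          ATf <- sum(As)
          densF <- drop(exp(params$kappaF * cos(outer(grid, mus, "-"))) %*%
                          (As / ATf)) / norm_f
        }
      }

      # spot component
      ATs <- 0
      if (has_spots) {
        musS <- numeric(0); AsS <- numeric(0)
        for (j in seq_along(spots)) {
          p <- .spot_percept(fpos, fheading, spots[[j]], half_fov)
          if (!is.null(p)) { musS <- c(musS, p[1]); AsS <- c(AsS, p[2]) }
        }
        if (length(AsS) > 0) {
          ATs <- sum(AsS)
          densS <- drop(exp(params$kappaS * cos(outer(grid, musS, "-"))) %*%
                          (AsS / ATs)) / norm_s
        }
      }

      # global mixture (Eq 2.11 weighting)
      w <- select_weights(wall$d, params, fish_present = n > 1,
                          spots_present = has_spots)
      wf <- if (ATf > 0) w$alpha_star * ATf else 0
      ws <- if (ATs > 0) w$beta_star * ATs else 0
      if (wf > 0) dens <- dens + wf * densF
      if (ws > 0) dens <- dens + ws * densS
      dens <- dens / (1 + wf + ws)

      # one speed draw then one direction draw, agents in id order
      regime <- if (!has_spots) "homogeneous" else if (under_spot(fpos, spots)$under) "under_spot" else "outside_spot"
      v <- sample_speed(regime, config$speeds, 1)
      cdf <- c(0, cumsum((dens[-1] + dens[-ng]) * (h / 2)))
      cdf <- cdf / cdf[ng]
      u <- stats::runif(1)
      k <- findInterval(u, cdf, all.inside = TRUE)
      theta <- grid[k] + (u - cdf[k]) / (cdf[k + 1] - cdf[k]) * h

      heading <- wrap_angle(fheading + theta)
      new_st[i, 1:2] <- .advance_position(fpos, heading, v * config$dt, a$side)
      new_st[i, 3] <- heading
      new_st[i, 4] <- v
    }
    st <- new_st
    if (step %% config$record_every == 0L) record(step)
  }

  df <- data.frame(time_s = rec[, 1], agent_id = as.integer(rec[, 2]),
                   x_m = rec[, 3], y_m = rec[, 4])
  df <- df[order(df$agent_id, df$time_s), ]
  rownames(df) <- NULL
  out <- trajectory_set(df, interval = config$record_interval,
                        arena_side = a$side)
  attr(out, "n_updates") <- config$n_steps
  attr(out, "seed") <- config$seed
  out
}
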