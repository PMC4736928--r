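# File formats and configuration: plain delimited trajectory tables and a
# YAML run configuration with Table-of-parameters defaults. All files use
# SI units (metres, seconds, radians).

#' Write trajectories to a delimited text file
#'
#' Comma-separated with header `time_s,agent_id,x_m,y_m`, one row per agent
#' per recorded frame; positions keep 15 significant digits so a round trip
#' is lossless at 1e-9 m.
#'
#' @param trajs a [trajectory_set()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(inherits(trajs, "trajectory_set"))
  df <- as.data.frame(trajs)
  utils::write.csv(df[, c("time_s", "agent_id", "x_m", "y_m")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from a delimited text file
#'
#' @param path file written by [write_trajectories()] (or any table with
#'   the same four columns).
#' @param arena_side declared arena side in metres used to validate
#'   positions (default: no bound).
#' @return a [trajectory_set()]; the sampling interval is inferred from the
#'   time base, which must be uniform.
#' @export
read_trajectories <- function(path, arena_side = Inf) {
  if (!file.exists(path)) stop(sprintf("read_trajectories: no such file '%s'", path))
  nf <- utils::count.fields(path, sep = ",")
  bad <- which(nf != 4)
  if (length(bad) > 0) {
    stop(sprintf("read_trajectories: malformed row at line %d of '%s' (%d fields, expected 4)",
                 bad[1], path, nf[bad[1]]))
  }
  df <- utils::read.csv(path)
  if (!identical(names(df), c("time_s", "agent_id", "x_m", "y_m"))) {
    stop("read_trajectories: header must be 'time_s,agent_id,x_m,y_m'")
  }
  if (nrow(df) == 0) {
    return(trajectory_set(df, interval = NA_real_, arena_side = arena_side))
  }
  times <- sort(unique(df$time_s))
  interval <- if (length(times) > 1) {
    steps <- diff(times)
    if (diff(range(steps)) > 1e-9) {
      stop("read_trajectories: non-uniform time base")
    }
    steps[1]
  } else NA_real_
  trajectory_set(df, interval = interval, arena_side = arena_side)
}

# YAML 1.1 parses a bare `y` key as the boolean TRUE; map it back so spot
# entries can be written naturally as `- x: ..., y: ...`
.parse_spot <- function(s) {
  names(s)[names(s) %in% c("TRUE", "yes")] <- "y"
  do.call(spot, s[c("x", "y", intersect(names(s), c("radius", "height")))])
}

.config_defaults <- function() {
  list(arena_side = 1.2, spots = list(), n_agents = 1, duration_s = 3600,
       dt_s = 1 / 3, record_interval_s = 1, seed = NULL,
       params = list(), speeds = list())
}

#' Load a run configuration file
#'
#' YAML key-value document; unspecified keys take the fitted defaults
#' (kappa0 = 6.3, alpha0 = 55, dW = 0.05 m, dt = 1/3 s, arena side 1.2 m,
#' and so on). Valid top-level keys: `arena_side`, `spots` (list of maps
#' with `x`, `y` and optional `radius`, `height`), `n_agents`,
#' `duration_s`, `dt_s`, `record_interval_s`, `seed`, `params` (any
#' [behaviour_params()] argument except `body`; body dimensions via
#' `body_length`, `body_width`, `body_height`), and `speeds` (regime name
#' to `[mean, sd]`). An omitted seed is generated and recorded in the
#' returned configuration so any run can be replayed.
#'
#' @param path configuration file path, or `NULL` for all defaults.
#' @param verbose echo the fully resolved configuration.
#' @return a [run_config()].
#' @export
load_config <- function(path = NULL, verbose = FALSE) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop(sprintf("load_config: unknown key(s) %s; valid keys: %s",
                   paste0("'", unknown, "'", collapse = ", "),
                   paste(names(cfg), collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  par_args <- cfg$params
  body_args <- list(length = par_args$body_length, width = par_args$body_width,
                    height = par_args$body_height)
  body_args <- body_args[!vapply(body_args, is.null, logical(1))]
  par_args <- par_args[setdiff(names(par_args),
                               c("body_length", "body_width", "body_height"))]
  valid_par <- setdiff(names(formals(behaviour_params)), "body")
  unknown <- setdiff(names(par_args), valid_par)
  if (length(unknown) > 0) {
    stop(sprintf("load_config: unknown params key(s) %s; valid keys: %s",
                 paste0("'", unknown, "'", collapse = ", "),
                 paste(c(valid_par, "body_length", "body_width", "body_height"),
                       collapse = ", ")))
  }
  par_args$body <- do.call(body_model, body_args)
  params <- do.call(behaviour_params, par_args)
  speeds <- do.call(speed_model, cfg$speeds)
  a <- arena(cfg$arena_side)
  spots <- lapply(cfg$spots, .parse_spot)
  config <- run_config(arena = a, spots = spots, n_agents = cfg$n_agents,
                       duration = cfg$duration_s, dt = cfg$dt_s,
                       params = params, speeds = speeds, seed = cfg$seed,
                       record_interval = cfg$record_interval_s)
  if (verbose) {
    message(sprintf(
      "run_config: arena %.2f m, %d spot(s), %d agent(s), %g s at dt %g s, record %g s, seed %d",
      a$side, length(spots), config$n_agents, config$duration, config$dt,
      config$record_interval, config$seed))
    message(sprintf(
      "params: kappa0=%g kappaW=%g kappaF=%g kappaS=%g alpha0=%g alphaW=%g beta0=%g betaW=%g wF=%g wS=%g dW=%g",
      params$kappa0, params$kappaW, params$kappaF, params$kappaS,
      params$alpha0, params$alphaW, params$beta0, params$betaW,
      params$wF, params$wS, params$dW))
  }
  config
}

#' Load a synthetic-reference specification file
#'
#' YAML document with keys `arena_side`, `spots`, `speeds` (as in
#' [load_config()]) plus `kappa`, `duration_s`, `dt_record_s`, `n_agents`
#' `wall_bias` and `wall_band`.
#'
#' @param path file path, or `NULL` for all defaults.
#' @return a [reference_spec()].
#' @export
load_reference_spec <- function(path = NULL) {
  defaults <- list(arena_side = 1.2, spots = list(), speeds = list(),
                   kappa = 6.3, duration_s = 3600, dt_record_s = 1,
                   n_agents = 1, wall_bias = 1, wall_band = 0.15)
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop(sprintf("load_reference_spec: unknown key(s) %s; valid keys: %s",
                   paste0("'", unknown, "'", collapse = ", "),
                   paste(names(cfg), collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  spots <- lapply(cfg$spots, .parse_spot)
  reference_spec(speeds = do.call(speed_model, cfg$speeds),
                 kappa = cfg$kappa, arena = arena(cfg$arena_side),
                 spots = spots, duration = cfg$duration_s,
                 dt_record = cfg$dt_record_s, n_agents = cfg$n_agents,
                 wall_bias = cfg$wall_bias, wall_band = cfg$wall_band)
}

#' Write an occupancy grid as a dense matrix text file
#'
#' @param grid matrix from [occupancy_grid()].
#' @param path destination path (tab-delimited, no header).
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(grid, path) {
  utils::write.table(grid, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}
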