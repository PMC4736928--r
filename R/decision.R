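# Circular decision model: the probability density over candidate headings
# is a normalized mixture of von Mises components contributed by the
# baseline/wall behaviour, perceived fish, and perceived spots. A heading is
# drawn from the numerically integrated CDF by inverse transform sampling.
# All densities live in the body frame: theta = 0 means "keep heading".

#' Behavioural parameters
#'
#' All tunable parameters of the decision model with their fitted defaults:
#' von Mises concentrations for basic swimming (`kappa0` = 6.3),
#' wall-following (`kappaW` = 20), fish stimuli (`kappaF` = 20) and spot
#' stimuli (`kappaS` = 20); per-steradian stimulus weights off-wall /
#' near-wall for fish (`alpha0` = 55, `alphaW` = 20) and spots
#' (`beta0` = 0.15, `betaW` = 0.01); the division factors applied to the
#' fish and spot weights when both stimulus kinds are present in the
#' environment (`wF` = 2, `wS` = 9); the wall-interaction distance
#' (`dW` = 0.05 m); the visual field (`fov` = 270 degrees); the decision
#' interval (`dt` = 1/3 s, matching the zebrafish tail-beat); and the fish
#' [body_model()].
#'
#' @param kappa0,kappaW,kappaF,kappaS von Mises concentrations (>= 0).
#' @param alpha0,alphaW fish-stimulus weights, per steradian (>= 0).
#' @param beta0,betaW spot-stimulus weights, per steradian (>= 0).
#' @param wF,wS mixed-condition division factors (>= 1).
#' @param dW wall-interaction distance in metres (> 0).
#' @param fov field of view in radians (default 3 pi / 2).
#' @param dt decision time step in seconds.
#' @param body a [body_model()].
#' @return an object of class `behaviour_params`.
#' @export
behaviour_params <- function(kappa0 = 6.3, kappaW = 20, kappaF = 20,
                             kappaS = 20, alpha0 = 55, alphaW = 20,
                             beta0 = 0.15, betaW = 0.01, wF = 2, wS = 9,
                             dW = 0.05, fov = 3 * pi / 2, dt = 1 / 3,
                             body = body_model()) {
  p <- list(kappa0 = kappa0, kappaW = kappaW, kappaF = kappaF,
            kappaS = kappaS, alpha0 = alpha0, alphaW = alphaW,
            beta0 = beta0, betaW = betaW, wF = wF, wS = wS, dW = dW,
            fov = fov, dt = dt, body = body)
  for (nm in c("kappa0", "kappaW", "kappaF", "kappaS",
               "alpha0", "alphaW", "beta0", "betaW")) {
    if (!.is_number(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("behaviour_params: '%s' must be a non-negative number", nm))
    }
  }
  if (p$wF < 1 || p$wS < 1) stop("behaviour_params: wF and wS must be >= 1")
  if (p$dW <= 0) stop("behaviour_params: dW must be > 0")
  if (p$fov <= 0 || p$fov > 2 * pi) stop("behaviour_params: fov must be in (0, 2*pi]")
  if (p$dt <= 0) stop("behaviour_params: dt must be > 0")
  stopifnot(inherits(body, "body_model"))
  structure(p, class = "behaviour_params")
}

#' Modified Bessel function of the first kind, order zero
#'
#' Direct summation of the defining series
#' I0(kappa) = sum_k (kappa/2)^(2k) / (k! Gamma(k + 1)),
#' accumulated until the relative contribution of a term drops below 1e-12.
#'
#' @param kappa non-negative argument (vectorized).
#' @return I0 evaluated at `kappa`.
#' @export
bessel_i0 <- function(kappa) {
  if (any(kappa < 0)) stop("bessel_i0: kappa must be non-negative")
  vapply(kappa, function(k) {
    term <- 1
    total <- 1
    j <- 1
    while (term > 1e-12 * total) {
      term <- term * (k / 2)^2 / j^2
      total <- total + term
      j <- j + 1
    }
    total
  }, numeric(1))
}

#' von Mises probability density
#'
#' f(theta) = exp(kappa * cos(theta - mu)) / (2 pi I0(kappa)); the circular
#' analogue of the Gaussian with location `mu` and concentration `kappa`
#' (kappa = 0 gives the uniform density 1 / (2 pi)).
#'
#' @param theta angles in radians (vectorized).
#' @param mu location in radians.
#' @param kappa concentration (>= 0).
#' @return density values.
#' @export
von_mises_pdf <- function(theta, mu = 0, kappa = 1) {
  if (kappa < 0) stop("von_mises_pdf: kappa must be non-negative")
  exp(kappa * cos(theta - mu)) / (2 * pi * bessel_i0(kappa))
}

#' Uniform angular grid over \[-pi, pi\]
#'
#' Both endpoints are included so that trapezoidal integration spans the
#' full circle; the default resolution is 0.5 degrees (721 nodes).
#'
#' @param n number of grid nodes.
#' @return numeric vector of angles.
#' @export
direction_grid <- function(n = 721) {
  stopifnot(n >= 8)
  seq(-pi, pi, length.out = n)
}

#' Direction PDF container
#'
#' A circular density tabulated on a uniform angular grid over
#' \[-pi, pi\], with an optional numerically integrated CDF.
#'
#' @param density non-negative density values on `grid`.
#' @param grid angular grid from [direction_grid()].
#' @param cdf optional CDF values (filled by [pdf_to_cdf()]).
#' @return an object of class `direction_pdf`.
#' @export
direction_pdf <- function(density, grid = direction_grid(), cdf = NULL) {
  stopifnot(length(density) == length(grid), all(density >= 0))
  structure(list(grid = grid, density = density, cdf = cdf),
            class = "direction_pdf")
}

#' Baseline / wall-following heading density
#'
#' Far from any wall (`d >= dW`) the agent keeps swimming forward: a single
#' von Mises centred on theta = 0 with concentration `kappa0`. Within the
#' wall-interaction distance the density becomes an equal-weight (1/2, 1/2)
#' two-component von Mises mixture centred on the two body-frame directions
#' parallel to the nearest wall, with concentration `kappaW`.
#'
#' @param d distance to the nearest wall in metres (>= 0).
#' @param wall_dirs body-frame directions `(mu_w1, mu_w2)` along the nearest
#'   wall; required when `d < dW`.
#' @param params a [behaviour_params()].
#' @param grid angular grid.
#' @return a [direction_pdf()].
#' @export
baseline_pdf <- function(d, wall_dirs = NULL, params = behaviour_params(),
                         grid = direction_grid()) {
  stopifnot(d >= 0)
  if (d >= params$dW) {
    dens <- von_mises_pdf(grid, 0, params$kappa0)
  } else {
    if (is.null(wall_dirs) || length(wall_dirs) != 2) {
      stop("baseline_pdf: wall_dirs (mu_w1, mu_w2) required when d < dW")
    }
    dens <- 0.5 * von_mises_pdf(grid, wall_dirs[1], params$kappaW) +
      0.5 * von_mises_pdf(grid, wall_dirs[2], params$kappaW)
  }
  direction_pdf(dens, grid)
}

#' Solid-angle-weighted von Mises mixture for one stimulus kind
#'
#' Each percept contributes a von Mises component centred on its bearing,
#' weighted by the ratio of its captured solid angle to the total solid
#' angle captured by all percepts of that kind.
#'
#' @param percepts non-empty list of [percept()]s of a single kind.
#' @param kappa concentration for this stimulus kind.
#' @param grid angular grid.
#' @return a list with elements `pdf` (a [direction_pdf()]) and
#'   `total_solid_angle` (steradians).
#' @export
stimulus_mixture_pdf <- function(percepts, kappa, grid = direction_grid()) {
  if (length(percepts) == 0) {
    stop("stimulus_mixture_pdf: requires at least one percept")
  }
  mus <- vapply(percepts, function(p) p$bearing, numeric(1))
  As <- vapply(percepts, function(p) p$solid_angle, numeric(1))
  if (any(As <= 0)) stop("stimulus_mixture_pdf: solid angles must be > 0")
  AT <- sum(As)
  dens <- .vm_mixture_density(grid, mus, As / AT, kappa)
  list(pdf = direction_pdf(dens, grid), total_solid_angle = AT)
}

# weighted von Mises mixture density on a grid (weights sum to 1)
.vm_mixture_density <- function(grid, mus, weights, kappa) {
  norm <- 2 * pi * bessel_i0(kappa)
  m <- exp(kappa * cos(outer(grid, mus, "-")))
  drop(m %*% weights) / norm
}

#' Wall-dependent stimulus weights
#'
#' Selects the fish weight alpha* (alpha0 off-wall, alphaW near-wall) and
#' the spot weight beta* (beta0 / betaW) by wall proximity. When both
#' stimulus kinds are enabled in the scenario, the fitted single-stimulus
#' weights are divided by the mixed-condition factors `wF` and `wS`
#' (alpha0 = 55 becomes 27.5, alphaW = 20 becomes 10 at the defaults).
#'
#' @param d distance to the nearest wall in metres.
#' @param params a [behaviour_params()].
#' @param fish_present,spots_present whether the scenario contains fish and
#'   spot stimuli; the division factors apply only when both are `TRUE`.
#' @return named list with `alpha_star` and `beta_star` (per steradian).
#' @export
select_weights <- function(d, params = behaviour_params(),
                           fish_present = TRUE, spots_present = FALSE) {
  stopifnot(d >= 0)
  alpha <- if (d >= params$dW) params$alpha0 else params$alphaW
  beta <- if (d >= params$dW) params$beta0 else params$betaW
  if (isTRUE(fish_present) && isTRUE(spots_present)) {
    alpha <- alpha / params$wF
    beta <- beta / params$wS
  }
  list(alpha_star = alpha, beta_star = beta)
}

#' Global heading density
#'
#' Convex combination of the baseline density and the fish and spot mixture
#' densities, weighted by the total captured solid angles:
#' f = (f0 + alpha* A_Tf fF + beta* A_Ts fS) / (1 + alpha* A_Tf + beta* A_Ts).
#' Absent stimulus terms contribute a zero total solid angle.
#'
#' @param f0 baseline [direction_pdf()].
#' @param fF,fS fish and spot mixture [direction_pdf()]s, or `NULL`.
#' @param ATf,ATs total solid angles (steradians) captured by fish / spots.
#' @param alpha_star,beta_star weights from [select_weights()].
#' @return a [direction_pdf()].
#' @export
global_pdf <- function(f0, fF = NULL, fS = NULL, ATf = 0, ATs = 0,
                       alpha_star = 0, beta_star = 0) {
  wf <- if (is.null(fF)) 0 else alpha_star * ATf
  ws <- if (is.null(fS)) 0 else beta_star * ATs
  dens <- f0$density
  if (wf > 0) dens <- dens + wf * fF$density
  if (ws > 0) dens <- dens + ws * fS$density
  direction_pdf(dens / (1 + wf + ws), f0$grid)
}

#' Numerically integrate a direction PDF into its CDF
#'
#' Cumulative trapezoidal integration of the density over \[-pi, pi\],
#' renormalized so the final value is exactly 1.
#'
#' @param pdf a [direction_pdf()].
#' @return the same object with the `cdf` field filled.
#' @export
pdf_to_cdf <- function(pdf) {
  cdf <- pracma::cumtrapz(pdf$grid, pdf$density)[, 1]
  total <- cdf[length(cdf)]
  if (total <= 0) stop("pdf_to_cdf: degenerate all-zero density")
  pdf$cdf <- cdf / total
  pdf
}

#' Inverse transform sampling of a heading
#'
#' Linearly interpolates the inverse CDF at uniform(0, 1) draws. Within
#' flat CDF regions (zero density) ties resolve to the left grid node.
#'
#' @param pdf a [direction_pdf()] with its CDF computed (see
#'   [pdf_to_cdf()]).
#' @param u uniform(0, 1) draws (vectorized).
#' @return sampled body-frame angles in \[-pi, pi\].
#' @export
sample_direction <- function(pdf, u) {
  if (is.null(pdf$cdf)) pdf <- pdf_to_cdf(pdf)
  if (any(u < 0 | u > 1)) stop("sample_direction: u must lie in [0, 1]")
  stats::approx(pdf$cdf, pdf$grid, xout = u, ties = min)$y
}
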