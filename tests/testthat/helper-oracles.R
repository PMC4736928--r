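# Independent oracles used across the test files.

# (azimuth, elevation) -> 3D unit vector
sp_to_vec <- function(p) {
  c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
}

# Girard spherical excess: sum of interior angles minus pi, with the
# interior angles computed from tangent vectors (independent of L'Huilier)
girard_excess <- function(tri) {
  v <- lapply(1:3, function(i) sp_to_vec(tri[i, ]))
  ang <- vapply(1:3, function(i) {
    a <- v[[i]]
    b <- v[[(i %% 3) + 1]]
    cc <- v[[((i + 1) %% 3) + 1]]
    tb <- b - sum(a * b) * a
    tc <- cc - sum(a * cc) * a
    acos(min(max(sum(tb * tc) / sqrt(sum(tb^2) * sum(tc^2)), -1), 1))
  }, numeric(1))
  sum(ang) - pi
}

# uniformly random spherical triangle as a 3 x 2 (azimuth, elevation) matrix
random_triangle <- function() {
  m <- matrix(stats::rnorm(9), 3)
  m <- m / sqrt(rowSums(m^2))
  cbind(atan2(m[, 2], m[, 1]), asin(pmin(pmax(m[, 3], -1), 1)))
}

# direct series summation of the order-zero modified Bessel function
# (finite k as stated; independent of the package implementation)
series_i0 <- function(x, kmax = 40) {
  sum((x / 2)^(2 * (0:kmax)) / factorial(0:kmax)^2)
}

# draw n von Mises(mu, kappa) samples through the package's numeric-CDF
# sampler (convenience; the distributional tests assert against closed
# forms, not against this helper)
draw_vm <- function(n, mu = 0, kappa = 1) {
  pdf <- pdf_to_cdf(direction_pdf(von_mises_pdf(direction_grid(), mu, kappa)))
  sample_direction(pdf, stats::runif(n))
}

# trapezoidal integral of a direction_pdf density
pdf_mass <- function(pdf) pracma::trapz(pdf$grid, pdf$density)

# number of local maxima of a circular density sampled on a grid whose two
# endpoints represent the same angle
circular_mode_count <- function(density) {
  d <- density[-length(density)]
  n <- length(d)
  up <- d > d[c(n, 1:(n - 1))]
  down <- d >= d[c(2:n, 1)]
  sum(up & down)
}
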