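# Circular decision model: Bessel series, von Mises densities, baseline and
# stimulus mixtures, the global heading density, and inverse-CDF sampling.

test_that("Bessel I0 series matches direct summation and base besselI", {
  expect_equal(bessel_i0(0), 1)
  expect_equal(bessel_i0(1), series_i0(1, 30), tolerance = 1e-12)
  expect_equal(bessel_i0(2), series_i0(2, 40), tolerance = 1e-12)
  # frozen values from the series oracle
  expect_equal(bessel_i0(1), 1.2660658778, tolerance = 1e-9)
  expect_equal(bessel_i0(2), 2.2795853023, tolerance = 1e-9)
  # independent library implementation over a range
  kappas <- c(0.1, 0.5, 1, 2, 6.3, 20, 50)
  expect_equal(bessel_i0(kappas), besselI(kappas, 0), tolerance = 1e-10)
  expect_error(bessel_i0(-1), "non-negative")
})

test_that("von Mises density has the right limits, symmetry and mode", {
  th <- seq(-pi, pi, length.out = 11)
  expect_equal(von_mises_pdf(th, 0.7, 0), rep(1 / (2 * pi), 11))
  # symmetric about mu
  x <- seq(0.1, 3, length.out = 7)
  expect_equal(von_mises_pdf(1 + x, 1, 4), von_mises_pdf(1 - x, 1, 4))
  # mode height at kappa = 2 from the series oracle
  expect_equal(von_mises_pdf(0.3, 0.3, 2), exp(2) / (2 * pi * series_i0(2)),
               tolerance = 1e-10)
  # periodic
  expect_equal(von_mises_pdf(th + 2 * pi, 0.5, 3), von_mises_pdf(th, 0.5, 3))
})

test_that("baseline density switches between forward and wall-following", {
  params <- behaviour_params()
  far <- baseline_pdf(0.30, params = params)
  expect_equal(far$grid[which.max(far$density)], 0)  # mode straight ahead
  expect_equal(pdf_mass(far), 1, tolerance = 1e-6)
  # near a wall parallel to the heading: equal modes at 0 and pi
  near <- baseline_pdf(0.01, wall_dirs = c(0, pi), params = params)
  expect_equal(pdf_mass(near), 1, tolerance = 1e-6)
  i0 <- which.min(abs(near$grid))
  ipi <- which.min(abs(near$grid - pi))
  expect_equal(near$density[i0], near$density[ipi], tolerance = 1e-9)
  expect_equal(circular_mode_count(near$density), 2)
  # the two wall components carry exactly half the mass each: removing one
  # halves the density everywhere it dominates
  single <- von_mises_pdf(near$grid, 0, params$kappaW)
  other <- von_mises_pdf(near$grid, pi, params$kappaW)
  expect_equal(near$density, 0.5 * single + 0.5 * other, tolerance = 1e-12)
  expect_error(baseline_pdf(0.01, params = params), "wall_dirs")
})

test_that("stimulus mixtures weight components by solid angle", {
  params <- behaviour_params()
  p1 <- percept("fish", 0.5, 0.02)
  single <- stimulus_mixture_pdf(list(p1), params$kappaF)
  expect_equal(single$total_solid_angle, 0.02)
  expect_equal(single$pdf$density,
               von_mises_pdf(single$pdf$grid, 0.5, params$kappaF),
               tolerance = 1e-12)
  # equal solid angles at +/- b: symmetric about zero
  pair <- stimulus_mixture_pdf(list(percept("fish", 0.8, 0.01),
                                    percept("fish", -0.8, 0.01)), 20)
  dens <- pair$pdf$density
  expect_equal(dens, rev(dens), tolerance = 1e-12)
  expect_equal(pdf_mass(pair$pdf), 1, tolerance = 1e-6)
  # weights proportional to solid angles: a 3:1 pair puts 3x the mass on
  # the first component's side
  skew <- stimulus_mixture_pdf(list(percept("fish", 1.5, 0.03),
                                    percept("fish", -1.5, 0.01)), 20)
  g <- skew$pdf$grid
  mass_pos <- pracma::trapz(g[g >= 0], skew$pdf$density[g >= 0])
  expect_equal(mass_pos, 0.75, tolerance = 1e-3)
  expect_equal(skew$total_solid_angle, 0.04)
  expect_error(stimulus_mixture_pdf(list(), 20), "at least one")
})

test_that("wall-dependent weights implement the fitted values", {
  params <- behaviour_params()
  # single-stimulus conditions use the directly fitted weights
  expect_equal(select_weights(0.3, params, TRUE, FALSE)$alpha_star, 55)
  expect_equal(select_weights(0.01, params, TRUE, FALSE)$alpha_star, 20)
  expect_equal(select_weights(0.3, params, FALSE, TRUE)$beta_star, 0.15)
  expect_equal(select_weights(0.01, params, FALSE, TRUE)$beta_star, 0.01)
  # mixed condition divides by wF and wS
  mixed_far <- select_weights(0.3, params, TRUE, TRUE)
  expect_equal(mixed_far$alpha_star, 27.5)
  expect_equal(mixed_far$beta_star, 0.15 / 9)
  expect_equal(select_weights(0.01, params, TRUE, TRUE)$alpha_star, 10)
})

test_that("global density is the normalized convex combination", {
  params <- behaviour_params()
  f0 <- baseline_pdf(0.3, params = params)
  # no stimuli: identical to the baseline
  expect_equal(global_pdf(f0)$density, f0$density)
  fF <- stimulus_mixture_pdf(list(percept("fish", 1.2, 0.05)), 20)
  fS <- stimulus_mixture_pdf(list(percept("spot", -2.0, 0.9)), 20)
  g <- global_pdf(f0, fF$pdf, fS$pdf, fF$total_solid_angle,
                  fS$total_solid_angle, alpha_star = 27.5,
                  beta_star = 0.15 / 9)
  expect_true(all(g$density >= 0))
  expect_equal(pdf_mass(g), 1, tolerance = 1e-6)
  # explicit convex-combination identity
  wf <- 27.5 * fF$total_solid_angle
  ws <- (0.15 / 9) * fS$total_solid_angle
  manual <- (f0$density + wf * fF$pdf$density + ws * fS$pdf$density) /
    (1 + wf + ws)
  expect_equal(g$density, manual, tolerance = 1e-12)
  # dominant fish term: global density converges to the fish mixture
  gBig <- global_pdf(f0, fF$pdf, NULL, 1e8, 0, alpha_star = 55)
  expect_lt(max(abs(gBig$density - fF$pdf$density)), 1e-5)
})

test_that("numeric CDF is monotone, normalized and invertible", {
  unif <- pdf_to_cdf(direction_pdf(rep(1 / (2 * pi), 721)))
  # uniform density -> linear CDF
  expect_equal(unif$cdf, (unif$grid + pi) / (2 * pi), tolerance = 1e-9)
  vm <- pdf_to_cdf(direction_pdf(von_mises_pdf(direction_grid(), 0, 6.3)))
  expect_true(all(diff(vm$cdf) >= 0))
  expect_equal(vm$cdf[1], 0)
  expect_equal(vm$cdf[721], 1)
  # symmetric density: median at zero
  expect_equal(stats::approx(vm$grid, vm$cdf, xout = 0)$y, 0.5,
               tolerance = 1e-6)
  expect_error(pdf_to_cdf(direction_pdf(rep(0, 721))), "degenerate")
  # endpoint draws map to the grid endpoints
  expect_equal(sample_direction(unif, 0), -pi)
  expect_equal(sample_direction(unif, 1), pi)
  expect_error(sample_direction(unif, 1.5), "\\[0, 1\\]")
})

test_that("inverse-transform samples follow their target density", {
  set.seed(202)
  unif <- pdf_to_cdf(direction_pdf(rep(1 / (2 * pi), 721)))
  su <- sample_direction(unif, stats::runif(1e5))
  # interpolation can coincidentally duplicate a value in 1e5 draws
  expect_gt(suppressWarnings(stats::ks.test(su, "punif", -pi, pi))$p.value,
            0.01)
  # von Mises(0, 20): circular mean near 0, circular sd near 1/sqrt(20)
  sv <- draw_vm(1e5, 0, 20)
  cmean <- atan2(mean(sin(sv)), mean(cos(sv)))
  expect_lt(abs(cmean), 0.01)
  csd <- sqrt(-2 * log(sqrt(mean(sin(sv))^2 + mean(cos(sv))^2)))
  expect_lt(abs(csd - 1 / sqrt(20)) / (1 / sqrt(20)), 0.05)
  # chi-squared goodness of fit for an arbitrary mixture
  params <- behaviour_params()
  f0 <- baseline_pdf(0.01, wall_dirs = c(0.7, -2.44), params = params)
  fF <- stimulus_mixture_pdf(list(percept("fish", 1.9, 0.03),
                                  percept("fish", -0.4, 0.01)), 20)
  g <- pdf_to_cdf(global_pdf(f0, fF$pdf, NULL, fF$total_solid_angle,
                             alpha_star = 20))
  sm <- sample_direction(g, stats::runif(1e5))
  breaks <- seq(-pi, pi, length.out = 73)
  counts <- tabulate(findInterval(sm, breaks, all.inside = TRUE), 72)
  probs <- vapply(1:72, function(b) {
    xs <- seq(breaks[b], breaks[b + 1], length.out = 17)
    pracma::trapz(xs, stats::approx(g$grid, g$density, xout = xs)$y)
  }, numeric(1))
  # Monte-Carlo p-value: concentrated densities leave near-empty tail bins
  expect_gt(stats::chisq.test(counts, p = probs, rescale.p = TRUE,
                              simulate.p.value = TRUE, B = 2000)$p.value,
            0.01)
})

test_that("two symmetric percepts shift from choice to compromise", {
  # two equal-solid-angle fish at +/- b, kappa = 20: bimodal (choice) for
  # wide separations, unimodal towards the bisector (compromise) for
  # narrow ones, with a transition in between
  mode_count_at <- function(b) {
    mix <- stimulus_mixture_pdf(list(percept("fish", b, 0.01),
                                     percept("fish", -b, 0.01)), 20)
    circular_mode_count(mix$pdf$density)
  }
  expect_equal(mode_count_at(1.4), 2)
  expect_equal(mode_count_at(0.05), 1)
  lo <- 0.05; hi <- 1.4
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (mode_count_at(mid) == 1) lo <- mid else hi <- mid
  }
  expect_gt(lo, 0)
  expect_lt(hi, pi / 2)
  # the compromise mode points at the bisector
  mix <- stimulus_mixture_pdf(list(percept("fish", 0.05, 0.01),
                                   percept("fish", -0.05, 0.01)), 20)
  expect_equal(mix$pdf$grid[which.max(mix$pdf$density)], 0)
})

test_that("every produced direction PDF integrates to one", {
  params <- behaviour_params()
  cases <- list(
    baseline_pdf(0.5, params = params),
    baseline_pdf(0.001, wall_dirs = c(1.2, 1.2 - pi), params = params),
    stimulus_mixture_pdf(list(percept("fish", 2.8, 0.004)), 20)$pdf,
    stimulus_mixture_pdf(list(percept("spot", -1, 0.5),
                              percept("spot", 1, 1.5)), 20)$pdf)
  for (pdf in cases) expect_equal(pdf_mass(pdf), 1, tolerance = 1e-6)
  g <- global_pdf(cases[[2]], cases[[3]], cases[[4]], 0.004, 2,
                  alpha_star = 20, beta_star = 0.01)
  expect_equal(pdf_mass(g), 1, tolerance = 1e-6)
})

test_that("behaviour parameter defaults and validation follow the fitted table", {
  p <- behaviour_params()
  expect_equal(p$kappa0, 6.3)
  expect_equal(p$kappaW, 20)
  expect_equal(p$alpha0, 55)
  expect_equal(p$alphaW, 20)
  expect_equal(p$beta0, 0.15)
  expect_equal(p$betaW, 0.01)
  expect_equal(p$wF, 2)
  expect_equal(p$wS, 9)
  expect_equal(p$dW, 0.05)
  expect_equal(p$fov, 3 * pi / 2)
  # the concentrations stay independently configurable
  p2 <- behaviour_params(kappaF = 12, kappaS = 35, kappaW = 8)
  expect_equal(c(p2$kappaF, p2$kappaS, p2$kappaW), c(12, 35, 8))
  expect_error(behaviour_params(kappa0 = -1), "non-negative")
  expect_error(behaviour_params(wF = 0.5), "wF")
  expect_error(behaviour_params(dW = 0), "dW")
})
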