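test_that("eccentricity and phase-function normalisation", {
  expect_equal(eccentricity_from_g(0), 0)
  expect_equal(eccentricity_from_g(0.6), 0.882353, tolerance = 1e-6)
  expect_lt(1 - eccentricity_from_g(1 - 1e-9), 1e-8)
  expect_error(eccentricity_from_g(1), "\\[0, 1\\)")
  expect_error(eccentricity_from_g(-0.1), "\\[0, 1\\)")
  for (g in c(0, 0.3, 0.6, 0.9)) {
    z <- stats::integrate(elliptical_pdf, -pi, pi, g = g,
                          rel.tol = 1e-12, abs.tol = 1e-12)$value
    expect_equal(z, 1, tolerance = 1e-9)
    # analytic mean cosine of the focus-polar elliptical density equals g
    mc <- stats::integrate(function(a) cos(a) * elliptical_pdf(a, g),
                           -pi, pi, rel.tol = 1e-12)$value
    expect_equal(mc, g, tolerance = 1e-9)
  }
})

test_that("elliptical sampler: mean cosine g, symmetry, uniform at g = 0", {
  set.seed(10)
  for (g in c(0, 0.3, 0.6, 0.9)) {
    a <- sample_elliptical(1e5, g)
    expect_true(all(a > -pi & a <= pi))
    se_c <- stats::sd(cos(a)) / sqrt(length(a))
    expect_lt(abs(mean(cos(a)) - g), 3 * se_c)
    se_s <- stats::sd(sin(a)) / sqrt(length(a))
    expect_lt(abs(mean(sin(a))), 3 * se_s)
  }
  ks <- suppressWarnings(stats::ks.test(sample_elliptical(1e4, 0),
                                        "punif", -pi, pi))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("free paths are exponential with mean lambda", {
  set.seed(11)
  l <- sample_free_path(1e5, 0.01)
  expect_lt(abs(mean(l) - 0.01), 3 * stats::sd(l) / sqrt(1e5))
  expect_lt(abs(mean(l > 0.01) - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e5))
  expect_error(sample_free_path(10, 0), "lambda")
})

test_that("diffusion coefficient and transport mean free path", {
  expect_equal(diffusion_coefficient(1, 0.01, 0), 0.005)
  expect_equal(diffusion_coefficient(1, 0.01, 0.5), 0.01)
  expect_equal(transport_mean_free_path(0.01, 0.6), 0.025)
  expect_error(diffusion_coefficient(1, 0.01, 1), "diverges")
})

test_that("crw_msd_oracle closed form agrees with brute-force Monte Carlo", {
  # limits first
  expect_equal(crw_msd_oracle(1, 0.01, 0.6), 2 * 0.01^2)
  expect_equal(crw_msd_oracle(7, 0.02, 0), 2 * 7 * 0.02^2)
  slope <- diff(crw_msd_oracle(c(500, 501), 0.01, 0.6))
  expect_equal(slope, 2 * 0.01^2 / (1 - 0.6), tolerance = 1e-6)
  # brute force at small n, independent of the package's walkers
  set.seed(12)
  for (g in c(0, 0.4)) {
    for (n in c(2, 5)) {
      r2 <- replicate(20000, {
        l <- rexp(n, 100)
        th <- cumsum(c(runif(1, -pi, pi), sample_elliptical(n - 1, g)))
        sum(l * -sin(th))^2 + sum(l * cos(th))^2
      })
      expect_lt(abs(mean(r2) - crw_msd_oracle(n, 0.01, g)),
                3 * stats::sd(r2) / sqrt(length(r2)))
    }
  }
})

test_that("simulated BW matches the MSD oracle and Poisson event count", {
  set.seed(13)
  msd <- bw_msd_events(bw_params(1, 0.01, 0.6), n_walkers = 4000,
                       n_events = 30)
  oracle <- crw_msd_oracle(1:30, 0.01, 0.6)
  # relative MC error of a squared-displacement mean is ~ 1.3 / sqrt(n)
  expect_true(all(abs(msd / oracle - 1) < 4 * 1.3 / sqrt(4000)))
  # total path length over n events ~ n * lambda
  sim <- simulate_bw(bw_params(1, 0.01, 0.6), R = Inf, max_events = 2000)
  len <- sum(sqrt(diff(sim$x)^2 + diff(sim$y)^2))
  expect_lt(abs(len / (2000 * 0.01) - 1), 3 / sqrt(2000))
})

test_that("boundary crossing is exact and near-ballistic limit holds", {
  set.seed(14)
  for (k in 1:5) {
    sim <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = 0.2)
    expect_true(sim$meta$exited)
    n <- length(sim$x)
    expect_equal(sqrt(sim$x[n]^2 + sim$y[n]^2), 0.2, tolerance = 1e-12)
    expect_true(all(sqrt(sim$x[-n]^2 + sim$y[-n]^2) < 0.2))
    # exit heading is the angle of the crossing point, package convention
    expect_equal(sim$meta$exit_heading,
                 atan2(-sim$x[n], sim$y[n]))
  }
  # g ~ 1: near-ballistic, net displacement ~ path length within 1%
  sim <- simulate_bw(bw_params(1, 0.01, 0.999), R = Inf, max_events = 5)
  net <- sqrt(sim$x[6]^2 + sim$y[6]^2)
  len <- sum(sqrt(diff(sim$x)^2 + diff(sim$y)^2))
  expect_gt(net / len, 0.99)
  # capped run is flagged
  capped <- simulate_bw(bw_params(0.015, 0.001, 0), R = 0.2, max_events = 10)
  expect_true(capped$meta$capped)
  expect_true(capped$censored)
})

test_that("simulations are reproducible under set.seed", {
  set.seed(99); a <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = 0.2)
  set.seed(99); b <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = 0.2)
  expect_identical(a$x, b$x)
  expect_identical(a$meta$exit_heading, b$meta$exit_heading)
})
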