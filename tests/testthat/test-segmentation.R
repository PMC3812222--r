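test_that("fit_segment projects endpoints onto the principal axis", {
  f <- fit_segment(rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(f$start, c(0, 0))
  expect_equal(f$end, c(2, 0))
  expect_equal(f$max_error, 0)

  # hand eigen-decomposition: cov of {(0,0),(1,1),(2,0)} is diagonal with
  # var_x > var_y, so the axis is horizontal through the centroid y = 1/3
  f2 <- fit_segment(rbind(c(0, 0), c(1, 1), c(2, 0)))
  expect_equal(f2$start, c(0, 1 / 3))
  expect_equal(f2$end, c(2, 1 / 3))
  expect_equal(f2$max_error, 2 / 3)

  # eigenvalue tie (square corners): axis falls back to the first-last chord
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  f3 <- fit_segment(sq)
  d <- f3$end - f3$start
  chord <- sq[4L, ] - sq[1L, ]
  expect_equal(abs(sum(d * chord) / sqrt(sum(d^2)) / sqrt(sum(chord^2))), 1)

  expect_error(fit_segment(rbind(c(1, 2), c(1, 2), c(1, 2))), "degenerate")
})

test_that("compute_deviations wraps into (-pi, pi]", {
  expect_equal(compute_deviations(c(pi / 4, pi / 2)), pi / 4)
  expect_equal(compute_deviations(c(3 * pi / 4, -3 * pi / 4)), pi / 2)
  expect_equal(compute_deviations(c(0.2, 0.2)), 0)
  expect_error(compute_deviations(0.2), "at least 2")
})

test_that("scale_criterion is linear in mean speed", {
  expect_equal(scale_criterion(1e-3, 0.02, 0.02), 1e-3)
  expect_equal(scale_criterion(1e-3, 0.02 / 3, 0.02), 1e-3 / 3)
  expect_error(scale_criterion(1e-3, 0.02, 0), "reference_speed")
  expect_error(scale_criterion(1e-3, -1, 0.02), "mean_speed")
})

test_that("collinear series collapse to one segment, an L to two", {
  tr <- trajectory(seq(0, 0.2, length.out = 200), rep(0, 200), (0:199) * 0.04)
  s <- segment_trajectory(tr, epsilon = 1e-6)
  expect_equal(nrow(s$segments), 1L)

  n <- 51
  x <- c(seq(0, 0.1, length.out = n), rep(0.1, n - 1))
  y <- c(rep(0, n), seq(0.002, 0.1, length.out = n - 1))
  L <- trajectory(x, y, seq_along(x) * 0.04)
  sL <- segment_trajectory(L, epsilon = 1e-3)
  expect_equal(nrow(sL$segments), 2L)
  expect_equal(abs(sL$deviations), pi / 2, tolerance = 1e-6)
  expect_error(segment_trajectory(L, epsilon = -1), "epsilon")
})

test_that("every point stays within epsilon of its segment axis", {
  set.seed(21)
  res <- add_tracking_noise(
    resample_constant_rate(
      simulate_bw(bw_params(0.015, 0.01, 0.6), R = Inf, max_events = 80),
      0.015, 0.04), 2e-4)
  eps <- 6e-4
  s <- segment_trajectory(res, eps)
  for (i in seq_len(nrow(s$segments))) {
    span <- s$segments$span_start[i]:s$segments$span_end[i]
    f <- fit_segment(cbind(res$x[span], res$y[span]))
    expect_lte(f$max_error, eps + 1e-12)
  }
})

test_that("segment count is non-increasing in epsilon; eps -> Inf gives 1", {
  set.seed(22)
  res <- resample_constant_rate(
    simulate_bw(bw_params(0.015, 0.01, 0.6), R = Inf, max_events = 120),
    0.015, 0.04)
  counts <- vapply(c(5e-5, 1.5e-4, 6e-4, 2e-3, 1e-2),
                   function(e) nrow(segment_trajectory(res, e)$segments), 1L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(nrow(segment_trajectory(res, 10)$segments), 1L)
})

test_that("greedy matches an exhaustive breakpoint search on tiny series", {
  # exhaustive oracle: minimal number of segments over all breakpoint
  # subsets such that every segment's fitted max error is within eps
  exhaustive_min_segments <- function(x, y, eps) {
    n <- length(x)
    ok <- function(a, b) fit_segment(cbind(x[a:b], y[a:b]))$max_error <= eps
    best <- n - 1L
    interior <- 2:(n - 1L)
    for (mask in 0:(2^length(interior) - 1L)) {
      br <- c(1L, interior[bitwAnd(bitwShiftR(mask, seq_along(interior) - 1L),
                                   1L) == 1L], n)
      k <- length(br) - 1L
      if (k >= best) next
      valid <- all(vapply(seq_len(k),
                          function(i) ok(br[i], br[i + 1L]), TRUE))
      if (valid) best <- k
    }
    best
  }
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    x <- cumsum(runif(n, 0.5, 1.5))
    y <- cumsum(rnorm(n, 0, 0.4))
    eps <- runif(1, 0.05, 0.5)
    tr <- trajectory(x, y, seq_len(n))
    s <- segment_trajectory(tr, eps)
    expect_true(all(s$segments$max_error <= eps + 1e-12))
    expect_lte(exhaustive_min_segments(x, y, eps), nrow(s$segments))
  }
})

test_that("noise-free recovery: lambda within 10%, g within 0.05", {
  set.seed(31)
  lam <- 0.01; g <- 0.6
  lam_hat <- g_hat <- numeric(6)
  for (k in 1:6) {
    sim <- simulate_bw(bw_params(0.015, lam, g), R = Inf, max_events = 400)
    res <- resample_constant_rate(sim, 0.015, 0.04)
    s <- segment_trajectory(res, epsilon = (0.015 * 0.04) / 5)
    lam_hat[k] <- mean(s$segments$length)
    g_hat[k] <- mean(cos(s$deviations))
  }
  expect_lt(abs(mean(lam_hat) / lam - 1), 0.10)
  expect_lt(abs(mean(g_hat) - g), 0.05)
})

test_that("as_segmented reproduces turning points exactly", {
  set.seed(8)
  sim <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = Inf, max_events = 40)
  s <- as_segmented(sim)
  expect_equal(nrow(s$segments), 40L)
  expect_equal(s$segments$length,
               sqrt(diff(sim$x)^2 + diff(sim$y)^2))
  expect_equal(s$segments$heading, sim$meta$headings, tolerance = 1e-12)
  expect_equal(max(s$segments$max_error), 0)
})
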