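test_that("sector_of implements half-open arcs centered on sector axes", {
  p <- sector_partition(8)
  expect_equal(sector_of(0, p), 0L)          # uphill
  expect_equal(sector_of(pi, p), 4L)         # downhill
  expect_equal(sector_of(pi / 8, p), 1L)     # boundary goes to upper sector
  expect_equal(sector_of(-pi / 8, p), 0L)    # lower edge included
  expect_equal(sector_of(2 * pi + 0.1, p), sector_of(0.1, p))
  expect_equal(sector_of(-pi, p), 4L)
  expect_error(sector_partition(7), "even")
  # every angle lands in exactly one sector; centers map to their own index
  expect_equal(sector_of(p$centers, p), 0:7)
})

test_that("build_ecdf endpoints, monotonicity and DKW closeness", {
  e <- build_ecdf(c(1, 2, 3), B = 10)
  expect_equal(e$F[1L], 0)
  expect_equal(e$F[length(e$F)], 1)
  expect_true(all(diff(e$F) >= 0))
  expect_equal(range(e$a), c(1, 3))

  set.seed(20)
  u <- runif(1e4)
  eu <- build_ecdf(u, B = 100)
  # uniform source: F(a) ~ a on [0,1] within the DKW-style band
  expect_lt(max(abs(eu$F - (eu$a - min(u)) / diff(range(u)))), 0.03)

  d <- build_ecdf(rep(2.5, 10))
  expect_true(d$degenerate)
  expect_equal(sample_ecdf(d, 5), rep(2.5, 5))
})

test_that("sample_ecdf inverse interpolation and distribution round trip", {
  # two-point grid: pure linear interpolation of r
  F2 <- structure(list(a = c(0, 1), F = c(0, 1), degenerate = FALSE,
                       n = 2, mean = 0.5), class = "bw_ecdf")
  set.seed(21)
  r <- runif(1e4)
  set.seed(21)
  expect_equal(sample_ecdf(F2, 1e4), r)

  # sampling a built ECDF reproduces the source distribution (KS < 0.05)
  set.seed(22)
  x <- rexp(1e4, 50)
  ex <- build_ecdf(x, B = 100)
  xs <- sample_ecdf(ex, 1e4)
  D <- suppressWarnings(stats::ks.test(x, xs))$statistic
  expect_lt(unname(D), 0.05)
  expect_true(all(xs >= min(x) & xs <= max(x)))

  # uniform source through the ECDF stays uniform
  eu <- build_ecdf(runif(1e4), B = 100)
  ksu <- suppressWarnings(stats::ks.test(sample_ecdf(eu, 1e4), "punif",
                                         min(eu$a), max(eu$a)))
  expect_lt(unname(ksu$statistic), 0.02)
})

test_that("estimate_sector_stats is isotropic for the standard BW", {
  set.seed(23)
  sim <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = Inf,
                     max_events = 40000)
  st <- estimate_sector_stats(as_segmented(sim))
  tab <- st$table
  expect_false(any(tab$empty))
  expect_equal(sum(tab$p), 1)
  expect_true(all(abs(tab$mean_free_path / 0.01 - 1) < 0.05))
  expect_lt(diff(range(tab$mean_free_path)) / mean(tab$mean_free_path), 0.1)
  expect_true(all(abs(tab$persistence - 0.6) < 0.05))
  # speed is constant by construction
  expect_true(all(abs(tab$mean_speed - 0.015) < 1e-9))
})

test_that("sector conventions: own heading for lengths, pre-turn for turns", {
  # two segments: first uphill (sector 0), second at a right angle; the
  # single deviation must be attributed to the pre-turn sector 0
  s <- make_segmented(headings = c(0, -pi / 2), lengths = c(0.02, 0.04))
  st <- estimate_sector_stats(s)
  s2 <- sector_of(-pi / 2, st$part)
  expect_equal(s2, 6L)  # -pi/2 is a quarter turn clockwise from uphill
  expect_equal(st$table$n[st$table$sector == 0], 1L)
  expect_equal(st$table$n[st$table$sector == s2], 1L)
  expect_equal(st$table$n_dev[st$table$sector == 0], 1L)
  expect_equal(sum(st$table$n_dev), 1L)
  expect_equal(st$table$mean_free_path[1L], 0.02)

  # all segments uphill: p_0 = 1, all other sectors empty-flagged
  su <- make_segmented(headings = rep(0, 5), lengths = rep(0.02, 5))
  stu <- estimate_sector_stats(su)
  expect_equal(stu$table$p[1L], 1)
  expect_true(all(stu$table$empty[-1L]))
  expect_equal(stu$table$mean_free_path[1L], 0.02)
  # simulation from stats with empty sectors refuses to run
  expect_error(simulate_extended_bw(stu), "empty sector")
})

test_that("mirror symmetry: reflecting headings reflects the sector stats", {
  set.seed(24)
  th <- runif(4000, -pi, pi)
  lens <- rexp(4000, 100)
  a <- estimate_sector_stats(make_segmented(th, lens))
  b <- estimate_sector_stats(make_segmented(-th, lens))
  S <- a$part$S
  mirror <- (S - a$table$sector) %% S
  expect_equal(b$table$n, a$table$n[mirror + 1L])
  expect_equal(b$table$mean_free_path, a$table$mean_free_path[mirror + 1L])
  expect_equal(b$table$persistence, a$table$persistence[mirror + 1L],
               tolerance = 1e-12)
  for (s in 0:(S - 1L)) {
    ea <- a$deviation_ecdf[[s + 1L]]; eb <- b$deviation_ecdf[[mirror[s + 1L] + 1L]]
    if (is.null(ea) || is.null(eb)) next
    expect_equal(eb$mean, -ea$mean, tolerance = 1e-12)
    expect_equal(range(eb$a), -rev(range(ea$a)), tolerance = 1e-12)
  }
})

test_that("extended walker preserves isotropy end to end", {
  set.seed(25)
  ok <- logical(5)
  for (b in 1:5) {
    sim <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = Inf,
                       max_events = 20000)
    st <- estimate_sector_stats(as_segmented(sim))
    h <- predict_exit_headings(st, N = 1000, R = 0.2)
    ok[b] <- hodges_ajne(h[is.finite(h)])$p > 0.05
  }
  expect_gte(sum(ok), 4L)  # flat exit headings in >= 90% of batches
})

test_that("round trip: extended walker reproduces the standard BW MSD", {
  set.seed(26)
  lam <- 0.01; g <- 0.6
  sim <- simulate_bw(bw_params(0.015, lam, g), R = Inf, max_events = 30000)
  st <- estimate_sector_stats(as_segmented(sim))
  walks <- replicate(2500, {
    tr <- simulate_extended_bw(st, R = Inf, max_events = 30)
    as_segmented(tr)
  }, simplify = FALSE)
  msd <- msd_vs_events(walks, n_max = 25)
  oracle <- crw_msd_oracle(msd$n, lam, g)
  # pooled overlapping windows: compare the curve within 5%
  expect_lt(mean(abs(msd$msd / oracle - 1)), 0.05)
})

test_that("constructed anisotropy shows up in the exit statistics", {
  set.seed(27)
  dev_sample <- sample_elliptical(4000, 0.6)
  len_iso <- rexp(4000, 100)            # lambda = 0.01
  part <- sector_partition(8)
  mk <- function(scale_vertical) {
    th <- runif(4000, -pi, pi)
    lens <- len_iso
    vert <- sector_of(th, part) %in% c(0L, 4L)
    lens[vert] <- lens[vert] * scale_vertical
    seg <- make_segmented(th, lens)
    seg$deviations <- dev_sample[seq_len(length(th) - 1L)]
    estimate_sector_stats(seg, part)
  }
  st2 <- mk(2)
  h <- predict_exit_headings(st2, N = 1000, R = 0.2)
  h <- h[is.finite(h)]
  ax <- abs(0.2 * sin(h)); ay <- abs(0.2 * cos(h))
  expect_gt(mean(ay), mean(ax))        # vertically elongated dispersal
  expect_lt(ks_two_sample(ax, ay)$p, 0.01)
  expect_lt(hodges_ajne(h)$p, 0.05)
})

test_that("deviation mass at zero yields near-straight exits", {
  set.seed(28)
  part <- sector_partition(8)
  th <- runif(2000, -pi, pi)
  seg <- make_segmented(th, rexp(2000, 100))
  seg$deviations <- rnorm(1999, 0, 1e-3)
  st <- estimate_sector_stats(seg, part)
  tr <- simulate_extended_bw(st, R = 0.2)
  expect_true(tr$meta$exited)
  # exit heading close to the initial heading
  expect_lt(abs(wrap_angle(tr$meta$exit_heading - tr$meta$headings[1L])),
            0.05)
})

test_that("sector stats serialise and restore", {
  set.seed(29)
  sim <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = Inf,
                     max_events = 3000)
  st <- estimate_sector_stats(as_segmented(sim))
  base <- file.path(withr::local_tempdir(), "stats")
  write_sector_stats(st, base)
  back <- read_sector_stats(base)
  expect_equal(back$table$mean_free_path, st$table$mean_free_path)
  expect_equal(back$table$persistence, st$table$persistence)
  expect_equal(back$global_speed, st$global_speed)
  for (s in 1:8) {
    expect_equal(back$length_ecdf[[s]]$a, st$length_ecdf[[s]]$a)
    expect_equal(back$deviation_ecdf[[s]]$F, st$deviation_ecdf[[s]]$F)
  }
  # simulation from the restored stats runs
  set.seed(1); h1 <- predict_exit_headings(st, N = 50)
  set.seed(1); h2 <- predict_exit_headings(back, N = 50)
  expect_identical(h1, h2)
})
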