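# shared synthetic-data helpers for the test suite

# von Mises sampler (Best & Fisher rejection), used for power checks
rvm <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1L]); f <- (1 + r * z) / (r + z); cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3L] - 0.5) * acos(f)
    }
  }
  out
}

# a straight constant-rate trajectory along a given heading
straight_traj <- function(n = 20, heading = 0, step = 0.01, dt = 0.04) {
  u <- c(-sin(heading), cos(heading))
  trajectory(u[1L] * step * (0:(n - 1L)), u[2L] * step * (0:(n - 1L)),
             dt * (0:(n - 1L)))
}

# fabricate a bw_segmented object from headings/lengths (unit durations)
make_segmented <- function(headings, lengths = rep(0.01, length(headings)),
                           durations = rep(1, length(headings))) {
  x <- cumsum(c(0, -lengths * sin(headings)))
  y <- cumsum(c(0, lengths * cos(headings)))
  seg <- data.frame(start_x = head(x, -1), start_y = head(y, -1),
                    end_x = x[-1], end_y = y[-1],
                    length = lengths, heading = headings,
                    duration = durations, max_error = 0,
                    span_start = seq_along(headings),
                    span_end = seq_along(headings) + 1L)
  structure(list(segments = seg,
                 deviations = if (length(headings) >= 2L)
                   compute_deviations(headings) else numeric(0),
                 breakpoints = seq_len(length(headings) + 1L),
                 epsilon = 0, meta = list(),
                 reorientation_x = x, reorientation_y = y),
            class = "bw_segmented")
}

# write a synthetic trajectory file in the 10-column dialect
write_synthetic_file <- function(traj, path, inclination = "0",
                                 individual = "1") {
  traj$meta$inclination_label <- inclination
  traj$meta$colony_label <- "A"
  traj$meta$temperature <- 25
  traj$meta$humidity <- 50
  traj$meta$date <- "2012-06-01"
  traj$meta$individual_index <- individual
  write_trajectory_file(traj, path, sidecar = FALSE)
  path
}

# simulate an ant-like tracked recording: standard BW to exit, resampled at
# 25 Hz, optional tracking noise
synthetic_ant <- function(v = 0.015, lambda = 0.01, g = 0.6, R = 0.22,
                          sigma = 0) {
  sim <- simulate_bw(bw_params(v, lambda, g), R = R)
  res <- resample_constant_rate(sim, v, 0.04)
  if (sigma > 0) res <- add_tracking_noise(res, sigma)
  res
}
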