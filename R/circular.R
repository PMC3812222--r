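#' Wrap an angle into (-pi, pi]
#'
#' @param a numeric vector of angles in radians (finite).
#' @return `a + 2*pi*k` mapped into the half-open interval (-pi, pi]; in
#'   particular `-pi` maps to `+pi`.
#' @export
wrap_angle <- function(a) {
  if (!all(is.finite(a))) stop("angles must be finite")
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- pi  # guard against floating-point landing exactly on -pi
  w
}

#' Axial summary statistics of circular data
#'
#' Summarises a sample of axial (bimodal, direction-insensitive) angles by
#' the angle-doubling construction: angles are doubled and reduced modulo
#' 2 pi, the mean vector of the doubled sample gives the mean resultant
#' length `R` and mean angle, the mean axis is half the doubled mean angle,
#' and the angular deviation of the doubled sample `sqrt(2 (1 - R))` is
#' halved to express dispersion on the original (axial) scale.
#'
#' @param angles numeric vector of angles in radians, n >= 1.
#' @return A list of class `bw_axial`: `mean_axis` in \[0, pi),
#'   `mean_resultant_length` in \[0, 1\], `angular_deviation` (radians, axial
#'   scale), and `n`. Errors when the doubled sample cancels exactly
#'   (`R = 0`), for which no axis is defined.
#' @export
axial_stats <- function(angles) {
  if (length(angles) < 1L) stop("need at least one angle")
  d <- (2 * angles) %% (2 * pi)
  X <- mean(cos(d)); Y <- mean(sin(d))
  R <- sqrt(X^2 + Y^2)
  if (R < 1e-12) stop("mean axis undefined: doubled sample has zero resultant")
  phi_star <- atan2(Y, X)            # mean angle of the doubled sample
  phi_bar <- (phi_star / 2) %% pi    # mean axis in [0, pi)
  s2 <- sqrt(2 * (1 - R))            # angular deviation of doubled sample
  structure(list(mean_axis = phi_bar, mean_resultant_length = R,
                 angular_deviation = s2 / 2, n = length(angles)),
            class = "bw_axial")
}

#' @export
print.bw_axial <- function(x, ...) {
  cat(sprintf(
    "<bw_axial> n = %d, mean axis = %.1f deg, R = %.3f, ang. dev. = %.1f deg\n",
    x$n, x$mean_axis * 180 / pi, x$mean_resultant_length,
    x$angular_deviation * 180 / pi))
  invisible(x)
}

#' Hodges-Ajne test of circular uniformity
#'
#' Omnibus uniformity test based on `m`, the minimum number of sample points
#' falling in any closed half-plane bounded by a diameter (computed by
#' sweeping the n diameters defined by the data). Small `m` indicates
#' concentration. Because any antipodally symmetric (balanced bimodal)
#' density puts exactly half its mass in every half-plane, the raw statistic
#' is blind to axial bimodality; with `axial = TRUE` (the default) angles are
#' doubled first, which folds opposite modes together and restores power
#' while leaving uniform samples uniform.
#'
#' The p-value is exact (`2^(1-n) * (n - 2m) * choose(n, m)`) for n <= 50 and
#' uses the large-sample approximation
#' `A = pi * sqrt(n) / (2 (n - 2 m))`, `p = sqrt(2 pi)/A * exp(-pi^2/(8 A^2))`
#' (capped at 1) above, avoiding factorial overflow.
#'
#' @param angles numeric vector of angles in radians, n >= 4.
#' @param axial double the angles before testing? Default `TRUE`.
#' @return A list `list(m, p, n, axial)`.
#' @export
hodges_ajne <- function(angles, axial = TRUE) {
  n <- length(angles)
  if (n < 4L) stop("Hodges-Ajne test needs at least 4 angles")
  if (!all(is.finite(angles))) stop("angles must be finite")
  th <- if (axial) (2 * angles) %% (2 * pi) else angles %% (2 * pi)
  a <- sort(th)
  # count points in [a_i, a_i + pi) for each data-defined diameter using a
  # circular two-pointer sweep on the doubled-around sorted sample
  aa <- c(a, a + 2 * pi)
  cnt <- integer(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < i + n && aa[j] < a[i] + pi) j <- j + 1L
    cnt[i] <- j - i
  }
  m <- min(pmin(cnt, n - cnt))
  if (2 * m >= n) {
    p <- 1  # data as balanced as possible: no evidence against uniformity
  } else if (n <= 50L) {
    p <- 2^(1 - n) * (n - 2 * m) * choose(n, m)
  } else {
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    p <- sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
  }
  list(m = m, p = min(1, p), n = n, axial = axial)
}

#' Windowed local headings of a trajectory
#'
#' Splits a trajectory into non-overlapping time windows (1 s by default) and
#' reports, for each window with at least 3 points and a non-degenerate point
#' cloud, the orientation of the first principal axis of the window's
#' coordinate covariance -- an axial heading in \[0, pi) on the package's
#' heading scale (0 = uphill). With `resolve_sign = TRUE` the axis is turned
#' into a direction in (-pi, pi] using the window's net displacement.
#'
#' @param traj a [trajectory()] object.
#' @param window window length in seconds (default 1).
#' @param resolve_sign resolve each axis to a direction by net displacement?
#' @return Numeric vector of headings; attribute `skipped` counts windows
#'   dropped as degenerate or too short.
#' @export
local_headings <- function(traj, window = 1.0, resolve_sign = FALSE) {
  stopifnot(inherits(traj, "bw_trajectory"), window > 0)
  br <- floor((traj$t - traj$t[1L]) / window)
  idx <- split(seq_along(traj$t), br)
  skipped <- 0L
  out <- numeric(0)
  for (ii in idx) {
    if (length(ii) < 3L) { skipped <- skipped + 1L; next }
    xs <- traj$x[ii]; ys <- traj$y[ii]
    cv <- stats::cov(cbind(xs, ys))
    if (!all(is.finite(cv)) || sum(diag(cv)) < .Machine$double.eps) {
      skipped <- skipped + 1L; next
    }
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    h <- heading_from_xy(ev[1L], ev[2L])
    if (resolve_sign) {
      dnet <- c(xs[length(xs)] - xs[1L], ys[length(ys)] - ys[1L])
      if (sum(ev * dnet) < 0) h <- wrap_angle(h + pi)
      out <- c(out, h)
    } else {
      out <- c(out, h %% pi)
    }
  }
  attr(out, "skipped") <- skipped
  out
}
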