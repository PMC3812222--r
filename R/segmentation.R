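#' Fit a straight segment to a cloud of consecutive points
#'
#' The fitted segment lies on the major axis of the point cloud: the
#' principal eigen-direction of the 2x2 coordinate covariance, through the
#' centroid. Its endpoints are the orthogonal projections of the first and
#' last point onto that axis, and the fit error is the maximum perpendicular
#' distance from any member point to the (infinite) axis line. When the two
#' eigenvalues tie (isotropic cloud) the axis closest to the chord from first
#' to last point is used.
#'
#' @param points a 2-column matrix (or data.frame) of x, y coordinates,
#'   at least 2 rows, not all identical.
#' @return A list: `start`, `end` (projected endpoints), `length`, `heading`
#'   (radians, package convention: 0 = uphill (+y), counterclockwise),
#'   `max_error` (m).
#' @export
fit_segment <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L || nrow(pts) < 2L)
    stop("points must be a 2-column matrix with >= 2 rows")
  ctr <- colMeans(pts)
  dc <- sweep(pts, 2, ctr)
  sxx <- sum(dc[, 1L]^2); syy <- sum(dc[, 2L]^2); sxy <- sum(dc[, 1L] * dc[, 2L])
  tr <- sxx + syy
  if (tr <= 0) stop("degenerate: all points identical")
  if (abs(sxx - syy) + 2 * abs(sxy) < 1e-14 * tr) {
    u <- pts[nrow(pts), ] - pts[1L, ]   # eigenvalue tie: use the chord
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else c(1, 0)
  } else {
    th <- 0.5 * atan2(2 * sxy, sxx - syy)
    u <- c(cos(th), sin(th))
  }
  proj <- function(p) ctr + sum((p - ctr) * u) * u
  s <- proj(pts[1L, ]); e <- proj(pts[nrow(pts), ])
  err <- max(abs(u[1L] * dc[, 2L] - u[2L] * dc[, 1L]))
  d <- e - s
  len <- sqrt(sum(d^2))
  heading <- if (len > 0) heading_from_xy(d[1L], d[2L]) else NA_real_
  list(start = unname(s), end = unname(e), length = len,
       heading = heading, max_error = err)
}

#' Smallest signed heading deviations
#'
#' Deviation at reorientation i is the wrapped difference between the
#' outgoing and incoming segment headings,
#' `alpha_i = ((theta_{i+1} - theta_i + pi) mod 2 pi) - pi`, mapped into
#' (-pi, pi].
#'
#' @param headings numeric vector of at least 2 headings (radians).
#' @return Numeric vector of length `length(headings) - 1`.
#' @export
compute_deviations <- function(headings) {
  if (length(headings) < 2L) stop("need at least 2 headings")
  wrap_angle(diff(headings))
}

#' Speed-scaled segmentation criterion
#'
#' The accepted error is ultimately a minimal resolvable turning angle, which
#' at fixed video rate depends on the spacing between points, hence on speed:
#' the criterion is scaled linearly, `eps = eps0 * mean_speed /
#' reference_speed`, so that slower (steeper-incline) recordings keep the
#' same angular resolution.
#'
#' @param eps0 baseline criterion (m) at the reference speed.
#' @param mean_speed observed mean speed (m/s), > 0.
#' @param reference_speed speed at which `eps0` was calibrated (m/s), > 0.
#' @return Scaled criterion in meters.
#' @export
scale_criterion <- function(eps0, mean_speed, reference_speed) {
  if (eps0 <= 0) stop("eps0 must be > 0")
  if (!is.finite(mean_speed) || mean_speed <= 0)
    stop("mean_speed must be > 0")
  if (!is.finite(reference_speed) || reference_speed <= 0)
    stop("reference_speed must be > 0")
  eps0 * mean_speed / reference_speed
}

#' Segment a trajectory into straight free paths
#'
#' Bottom-up piecewise-linear segmentation. The point series starts as the
#' finest partition (one segment per pair of consecutive points, total error
#' zero); pair merges (two adjacent segments into one) and triple merges
#' (three adjacent segments into two, split at the interior point minimising
#' error) are then applied greedily, always choosing the candidate whose
#' refitted maximum point-to-axis error is smallest, until no candidate stays
#' within `epsilon`. Every retained point is therefore within `epsilon` of
#' its segment's axis line.
#'
#' The default `epsilon` (0.6 mm) is calibrated so that sub-noise wiggles at
#' the tracker's sub-millimeter precision do not spawn segments at typical
#' ant point spacing; it should be adapted to the data (see
#' [scale_criterion()] for speed scaling).
#'
#' @param traj a [trajectory()] object with at least 3 points.
#' @param epsilon maximum accepted point-to-segment error (m).
#' @param speed_scaling scale `epsilon` by mean speed relative to
#'   `reference_speed`?
#' @param reference_speed reference speed for scaling (m/s).
#' @return An object of class `bw_segmented`: list with `segments` (a
#'   data.frame with columns start_x, start_y, end_x, end_y, length, heading,
#'   duration, max_error, span_start, span_end), `deviations` (signed, in
#'   (-pi, pi], length nrow(segments) - 1), `breakpoints` (indices into the
#'   source points), `epsilon` (the criterion actually used), and `meta`
#'   inherited from the trajectory.
#' @export
segment_trajectory <- function(traj, epsilon = 6e-4, speed_scaling = FALSE,
                               reference_speed = NULL) {
  stopifnot(inherits(traj, "bw_trajectory"))
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (length(traj$x) < 3L) stop("need at least 3 points to segment")
  eps <- epsilon
  if (speed_scaling) {
    if (is.null(reference_speed)) stop("speed_scaling needs reference_speed")
    eps <- scale_criterion(epsilon, path_length_and_speed(traj)$mean_speed,
                           reference_speed)
  }
  br <- cpp_segment_bottom_up(traj$x, traj$y, eps)
  segments_from_breakpoints(traj, br, eps)
}

# build the bw_segmented object from breakpoint indices (1-based, includes
# first and last point)
segments_from_breakpoints <- function(traj, br, eps) {
  ns <- length(br) - 1L
  seg <- data.frame(start_x = numeric(ns), start_y = numeric(ns),
                    end_x = numeric(ns), end_y = numeric(ns),
                    length = numeric(ns), heading = numeric(ns),
                    duration = numeric(ns), max_error = numeric(ns),
                    span_start = integer(ns), span_end = integer(ns))
  for (i in seq_len(ns)) {
    a <- br[i]; b <- br[i + 1L]
    f <- fit_segment(cbind(traj$x[a:b], traj$y[a:b]))
    seg$start_x[i] <- f$start[1L]; seg$start_y[i] <- f$start[2L]
    seg$end_x[i] <- f$end[1L]; seg$end_y[i] <- f$end[2L]
    seg$length[i] <- f$length; seg$heading[i] <- f$heading
    seg$duration[i] <- traj$t[b] - traj$t[a]; seg$max_error[i] <- f$max_error
    seg$span_start[i] <- a; seg$span_end[i] <- b
  }
  structure(
    list(segments = seg,
         deviations = if (ns >= 2L) compute_deviations(seg$heading)
                      else numeric(0),
         breakpoints = br, epsilon = eps, meta = traj$meta,
         reorientation_x = traj$x[br], reorientation_y = traj$y[br]),
    class = "bw_segmented")
}

#' Treat a turning-point trajectory as an exact segmentation
#'
#' Converts a polyline of turning points (e.g. the output of
#' [simulate_bw()] or [simulate_extended_bw()]) into a `bw_segmented`
#' object in which every pair of consecutive vertices is one exact free
#' path (max error 0). Useful for estimating sector statistics directly
#' from simulated walkers, bypassing the segmentation step.
#'
#' @param traj a [trajectory()] object whose vertices are turning points.
#' @return A `bw_segmented` object.
#' @export
as_segmented <- function(traj) {
  stopifnot(inherits(traj, "bw_trajectory"))
  segments_from_breakpoints(traj, seq_along(traj$x), eps = 0)
}

#' @export
print.bw_segmented <- function(x, ...) {
  ns <- nrow(x$segments)
  cat(sprintf(
    "<bw_segmented> %d segments (eps = %.3g m), mean free path %.4g m\n",
    ns, x$epsilon, mean(x$segments$length)))
  if (ns >= 2L)
    cat(sprintf("  persistence <cos alpha> = %.3f\n", mean(cos(x$deviations))))
  invisible(x)
}
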