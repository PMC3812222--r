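#' Mean square displacement versus reorientation events
#'
#' MSD indexed by the number of reorientation events rather than time, which
#' is insensitive to speed fluctuations and stops: for each `n <= n_max`,
#' the average of `|X_{k+n} - X_k|^2` over all start indices `k` of all
#' trajectories, where the `X_k` are the reorientation locations (segment
#' boundary points). Overlapping windows are pooled within and across
#' trajectories, so the confidence bounds are approximate (windows are
#' autocorrelated).
#'
#' @param segmented a `bw_segmented` object or a list of them (each with at
#'   least 2 reorientation locations).
#' @param n_max largest event count; must be attainable by at least one
#'   trajectory.
#' @return A data.frame of class `bw_msd`: `n`, `msd` (m^2), `lo`, `hi`
#'   (approximate 95% bounds), `count` (pooled window count per `n`).
#' @export
msd_vs_events <- function(segmented, n_max = 50L) {
  if (inherits(segmented, "bw_segmented")) segmented <- list(segmented)
  stopifnot(all(vapply(segmented, inherits, TRUE, "bw_segmented")))
  pts <- lapply(segmented, function(s) cbind(s$reorientation_x,
                                             s$reorientation_y))
  if (!any(vapply(pts, nrow, 1L) - 1L >= 1L))
    stop("need at least one trajectory with >= 2 reorientation locations")
  if (n_max > max(vapply(pts, nrow, 1L)) - 1L)
    stop("n_max exceeds every trajectory's event count")
  msd <- lo <- hi <- numeric(n_max)
  count <- integer(n_max)
  for (n in seq_len(n_max)) {
    sq <- unlist(lapply(pts, function(p) {
      m <- nrow(p) - n
      if (m < 1L) return(numeric(0))
      k <- seq_len(m)
      (p[k + n, 1L] - p[k, 1L])^2 + (p[k + n, 2L] - p[k, 2L])^2
    }))
    count[n] <- length(sq)
    if (count[n]) {
      msd[n] <- mean(sq)
      se <- stats::sd(sq) / sqrt(length(sq))
      lo[n] <- msd[n] - 1.96 * se
      hi[n] <- msd[n] + 1.96 * se
    } else {
      msd[n] <- lo[n] <- hi[n] <- NA_real_
    }
  }
  structure(data.frame(n = seq_len(n_max), msd = msd, lo = lo, hi = hi,
                       count = count),
            class = c("bw_msd", "data.frame"))
}

#' Per-individual time-averaged summary
#'
#' Summarises one preprocessed trajectory inside the exit circle: residence
#' time (s), trajectory length (m, stops included in time but not length),
#' mean speed, the time-averages of `|x|` and `|y|` relative to the start
#' (the horizontal/vertical dispersal proxies), and the exit heading
#' (censored trajectories have `exit_heading = NA` and `censored = TRUE`;
#' other fields are still computed). For sampled data the exit heading is
#' taken at the linear interpolation of the first outside-crossing step.
#'
#' @param traj a [trajectory()] object (ideally [trim_start()] +
#'   [truncate_exit()] output).
#' @param R exit radius (m).
#' @param center circle center; defaults to the recorded dropping site.
#' @return A one-row data.frame: mean_speed, residence_time,
#'   trajectory_length, mean_abs_x, mean_abs_y, exit_heading, censored.
#' @export
summarize_individual <- function(traj, R = 0.2, center = NULL) {
  stopifnot(inherits(traj, "bw_trajectory"))
  if (is.null(center)) {
    center <- if (!is.null(traj$meta$origin)) traj$meta$origin
              else c(traj$x[1L], traj$y[1L])
  }
  rx <- traj$x - center[1L]; ry <- traj$y - center[2L]
  tt <- traj$t
  dist <- sqrt(rx^2 + ry^2)
  outside <- which(dist > R)
  censored <- length(outside) == 0L
  eh <- NA_real_
  if (!censored) {
    # replace the first outside sample by the interpolated circle crossing,
    # so time, length and averages cover exactly the inside of the disk
    i <- outside[1L]
    p0 <- c(rx[i - 1L], ry[i - 1L]); p1 <- c(rx[i], ry[i])
    d <- p1 - p0
    aa <- sum(d^2); bb <- sum(p0 * d); cc <- sum(p0^2) - R^2
    s <- (-bb + sqrt(max(0, bb^2 - aa * cc))) / aa
    s <- min(max(s, 0), 1)
    ex <- p0 + s * d
    rx <- c(rx[seq_len(i - 1L)], ex[1L])
    ry <- c(ry[seq_len(i - 1L)], ex[2L])
    tt <- c(tt[seq_len(i - 1L)], tt[i - 1L] + s * (tt[i] - tt[i - 1L]))
    eh <- if (!is.null(traj$meta$exit_heading) &&
              is.finite(traj$meta$exit_heading))
            traj$meta$exit_heading   # exact intersection from the simulator
          else heading_from_xy(ex[1L], ex[2L])
  }
  last <- length(rx)
  # time-weighted averages (trapezoid on the sampling grid)
  tw <- function(v) {
    if (last < 2L || tt[last] == tt[1L]) return(v[1L])
    dt <- diff(tt)
    sum((v[-1L] + v[-last]) / 2 * dt) / sum(dt)
  }
  len <- sum(sqrt(diff(rx)^2 + diff(ry)^2))
  dur <- tt[last] - tt[1L]
  data.frame(mean_speed = if (dur > 0) len / dur else NA_real_,
             residence_time = dur, trajectory_length = len,
             mean_abs_x = tw(abs(rx)), mean_abs_y = tw(abs(ry)),
             exit_heading = eh, censored = censored)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] returning the maximum ECDF gap
#' `D` and its asymptotic p-value. Note that applying the linear KS test to
#' exit headings (circular support) ignores the wrap-around; this mirrors
#' common practice but is questionable for circular data.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @return A list `list(D, p)`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("both samples need >= 2 values")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}
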