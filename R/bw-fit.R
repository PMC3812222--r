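#' Fit a Boltzmann Walker model to trajectories
#'
#' The central estimator of the package. Each trajectory is preprocessed
#' (start trim to discard the settling-in phase, truncation at the first
#' exit from the radius-`R` circle around the dropping site), segmented into
#' straight free paths by bottom-up piecewise-linear segmentation, and the
#' pooled segments are partitioned by heading sector to estimate the
#' direction-dependent motion parameters of the extended Boltzmann Walker:
#' per-sector mean speed, mean free path, persistence (mean cosine of
#' turning deviations) and the empirical length/deviation distributions.
#' The isotropic (standard BW) parameters are the pooled equivalents.
#'
#' @param x a list of [trajectory()] objects, a character vector of
#'   trajectory file paths, or a single directory containing them.
#' @param epsilon segmentation criterion (m); see [segment_trajectory()].
#' @param sectors heading sector count (default 8).
#' @param trim start-trim distance (m); `NULL` skips trimming.
#' @param R exit-circle radius (m); `NULL` skips truncation.
#' @param speed_scaling,reference_speed optional per-trajectory speed
#'   scaling of `epsilon`, see [scale_criterion()].
#' @param B ECDF bin count for the sector distributions.
#' @return An object of class `bw_fit`: list with `trajectories`,
#'   `segmented`, `stats` (a [estimate_sector_stats()] object), `summaries`
#'   (one row per individual, see [summarize_individual()]), `params` (the
#'   pooled [bw_params()]), `epsilon`, `R`, `n_failed`, `call`.
#' @examples
#' set.seed(1)
#' ants <- replicate(8, {
#'   s <- simulate_bw(bw_params(0.015, 0.01, 0.6), R = 0.2)
#'   resample_constant_rate(s, 0.015, 0.04)
#' }, simplify = FALSE)
#' fit <- bw_fit(ants, epsilon = 2e-4, trim = NULL, R = 0.2)
#' fit
#' coef(fit)
#' @export
bw_fit <- function(x, epsilon = 6e-4, sectors = 8L, trim = 0.01, R = 0.2,
                   speed_scaling = FALSE, reference_speed = NULL,
                   B = 100L) {
  cl <- match.call()
  if (is.character(x)) {
    if (length(x) == 1L && dir.exists(x))
      x <- list.files(x, full.names = TRUE, pattern = "\\.(tsv|txt|dat)$")
    x <- lapply(x, read_trajectory_file)
  }
  stopifnot(length(x) >= 1L, all(vapply(x, inherits, TRUE, "bw_trajectory")))
  prep <- function(tr) {
    if (!is.null(trim)) tr <- trim_start(tr, trim)
    if (!is.null(R)) tr <- truncate_exit(tr, R)
    tr
  }
  prepped <- list(); segmented <- list(); summaries <- list()
  n_failed <- 0L
  for (tr in x) {
    res <- tryCatch({
      p <- prep(tr)
      s <- segment_trajectory(p, epsilon, speed_scaling = speed_scaling,
                              reference_speed = reference_speed)
      list(p = p, s = s)
    }, error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    prepped[[length(prepped) + 1L]] <- res$p
    segmented[[length(segmented) + 1L]] <- res$s
    summaries[[length(summaries) + 1L]] <-
      if (!is.null(R)) summarize_individual(res$p, R) else NULL
  }
  if (!length(segmented)) stop("no trajectory could be segmented")
  stats <- estimate_sector_stats(segmented, sector_partition(sectors), B)
  segs <- do.call(rbind, lapply(segmented, `[[`, "segments"))
  devs <- unlist(lapply(segmented, `[[`, "deviations"))
  gbar <- if (length(devs)) mean(cos(devs)) else NA_real_
  params <- bw_params(stats$global_speed, mean(segs$length),
                      max(0, min(gbar, 1 - 1e-9)))
  structure(
    list(trajectories = prepped, segmented = segmented, stats = stats,
         summaries = if (length(summaries) && !is.null(summaries[[1L]]))
                       do.call(rbind, summaries) else NULL,
         params = params, pooled_g = gbar, epsilon = epsilon, R = R,
         n_failed = n_failed, call = cl),
    class = "bw_fit")
}

#' @export
print.bw_fit <- function(x, ...) {
  cat("Boltzmann Walker fit\n")
  cat(sprintf("  %d trajectories (%d failed), %d segments, epsilon = %.3g m\n",
              length(x$segmented) + x$n_failed, x$n_failed,
              sum(x$stats$table$n), x$epsilon))
  cat(sprintf(
    "  pooled: v = %.4g m/s, lambda = %.4g m, g = %.3f, D = %.3g m^2/s\n",
    x$params$v, x$params$lambda, x$pooled_g,
    diffusion_coefficient(x$params$v, x$params$lambda,
                          min(x$pooled_g, 1 - 1e-9))))
  invisible(x)
}

#' @export
summary.bw_fit <- function(object, ...) {
  devs <- unlist(lapply(object$segmented, `[[`, "deviations"))
  heads <- unlist(lapply(object$segmented,
                         function(s) s$segments$heading))
  ha <- if (length(heads) >= 4L) hodges_ajne(heads) else NULL
  ax <- tryCatch(axial_stats(heads), error = function(e) NULL)
  out <- list(fit = object, sector_table = object$stats$table,
              n_deviations = length(devs), heading_test = ha,
              heading_axis = ax)
  class(out) <- "summary.bw_fit"
  out
}

#' @export
print.summary.bw_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-sector estimates (sector 0 = uphill):\n")
  print(x$sector_table[, c("sector", "n", "p", "mean_speed",
                           "mean_free_path", "persistence")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$heading_test))
    cat(sprintf(
      "\nHodges-Ajne uniformity of segment headings (axial): m = %d, p = %.3g\n",
      x$heading_test$m, x$heading_test$p))
  if (!is.null(x$heading_axis))
    cat(sprintf("Mean heading axis: %.1f deg, R = %.3f\n",
                x$heading_axis$mean_axis * 180 / pi,
                x$heading_axis$mean_resultant_length))
  invisible(x)
}

#' @export
coef.bw_fit <- function(object, which = c("global", "sector"), ...) {
  which <- match.arg(which)
  if (which == "global") {
    return(c(v = object$params$v, lambda = object$params$lambda,
             g = object$pooled_g))
  }
  tab <- object$stats$table
  m <- as.matrix(tab[, c("mean_speed", "mean_free_path", "persistence", "p")])
  dimnames(m) <- list(paste0("sector", tab$sector),
                      c("v", "lambda", "g", "p"))
  m
}

#' Simulate trajectories from a fitted Boltzmann Walker
#'
#' Draws `nsim` trajectories from the fitted model: either the extended
#' (heading-conditioned, sector-ECDF) walker or the standard isotropic
#' walker with the pooled parameters. Each run stops at the first exit from
#' the radius-`R` circle.
#'
#' @param object a [bw_fit()] object.
#' @param nsim number of trajectories.
#' @param seed optional seed passed to [set.seed()].
#' @param mode `"extended"` (default) or `"standard"`.
#' @param R exit radius (m); defaults to the fit's.
#' @param ... unused.
#' @return A list of [trajectory()] objects.
#' @export
simulate.bw_fit <- function(object, nsim = 1L, seed = NULL,
                            mode = c("extended", "standard"),
                            R = object$R, ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(R)) R <- 0.2
  replicate(nsim, {
    if (mode == "extended") simulate_extended_bw(object$stats, R = R)
    else simulate_bw(object$params, R = R)
  }, simplify = FALSE)
}

#' Predict the exit-heading distribution of a fitted walker
#'
#' @param object a [bw_fit()] object.
#' @param N number of simulated walkers (default 10000).
#' @param R exit radius (m).
#' @param ... unused.
#' @return Numeric vector of `N` predicted exit headings (radians,
#'   0 = uphill); see [predict_exit_headings()].
#' @export
predict.bw_fit <- function(object, N = 10000L, R = object$R, ...) {
  if (is.null(R)) R <- 0.2
  predict_exit_headings(object$stats, N = N, R = R)
}

#' Plot a fitted Boltzmann Walker
#'
#' Two base-graphics panels: a 16-bin rose histogram of segment headings
#' (display convention; estimation uses 8 sectors) and the observed MSD
#' versus reorientation events with the closed-form correlated-random-walk
#' curve at the pooled parameters.
#'
#' @param x a [bw_fit()] object.
#' @param n_max largest event count for the MSD panel.
#' @param bins rose-histogram bin count (default 16).
#' @param ... unused.
#' @export
plot.bw_fit <- function(x, n_max = NULL, bins = 16L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  heads <- unlist(lapply(x$segmented, function(s) s$segments$heading))
  br <- seq(-pi, pi, length.out = bins + 1L) + pi / bins
  h <- graphics::hist(wrap_angle(heads - pi / bins), breaks = br - pi / bins,
                      plot = FALSE)
  r <- sqrt(h$counts / max(h$counts))
  plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
       xlab = "", ylab = "", axes = FALSE, main = "segment headings")
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey")
  mid <- h$mids
  for (i in seq_along(mid)) {
    a0 <- mid[i] - pi / bins; a1 <- mid[i] + pi / bins
    aa <- seq(a0, a1, length.out = 10L)
    graphics::polygon(c(0, -r[i] * sin(aa), 0), c(0, r[i] * cos(aa), 0),
                      col = "grey70")
  }
  graphics::text(0, 1.08, "up"); graphics::text(0, -1.08, "down")
  ev <- max(3L, min(vapply(x$segmented,
                           function(s) nrow(s$segments), 1L)))
  if (is.null(n_max)) n_max <- min(50L, ev)
  msd <- msd_vs_events(x$segmented, n_max = n_max)
  plot(msd$n, msd$msd, pch = 16, cex = 0.6, xlab = "reorientation events",
       ylab = expression(MSD ~ (m^2)), main = "dispersal")
  graphics::lines(msd$n,
                  crw_msd_oracle(msd$n, x$params$lambda,
                                 max(0, min(x$pooled_g, 0.999))),
                  col = "red")
  invisible(x)
}
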