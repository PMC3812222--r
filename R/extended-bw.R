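#' Heading sector partition
#'
#' Partitions the heading circle into `S` half-open arcs of width `2 pi / S`
#' centered at `offset + 2 pi k / S`. With the default offset 0, sector 0 is
#' centered on the uphill direction and sector `S/2` on the downhill
#' direction. Estimation and simulation use 8 sectors by default; 16 is the
#' usual choice for display histograms.
#'
#' @param S sector count, even, >= 2 (default 8).
#' @param offset rotation of the partition in radians (default 0).
#' @return A list of class `bw_sectors` with elements `S`, `offset`,
#'   `centers`.
#' @export
sector_partition <- function(S = 8L, offset = 0) {
  S <- as.integer(S)
  if (S < 2L || S %% 2L != 0L) stop("S must be an even integer >= 2")
  structure(list(S = S, offset = offset,
                 centers = wrap_angle(offset + 2 * pi * (0:(S - 1L)) / S)),
            class = "bw_sectors")
}

#' Sector index of a heading
#'
#' @param theta heading(s) in radians (any finite value; wrapped).
#' @param part a [sector_partition()].
#' @return Zero-based sector index (vectorised): the half-open arc
#'   `[center - pi/S, center + pi/S)` containing `wrap_angle(theta)`.
#' @export
sector_of <- function(theta, part = sector_partition()) {
  stopifnot(inherits(part, "bw_sectors"))
  if (any(!is.finite(theta))) stop("theta must be finite")
  w <- 2 * pi / part$S
  phi <- (theta - part$offset + w / 2) %% (2 * pi)
  as.integer(floor(phi / w)) %% part$S
}

#' Discretised empirical CDF on a uniform grid
#'
#' Evaluates the step ECDF of a sample on a uniform `B`-bin abscissa grid
#' spanning the sample range, forcing the endpoints to exactly 0 and 1 (so
#' `F(a_0) = 0` by construction, at the cost of a vanishing bias at the
#' lower edge). This 100-bin discretisation is the representation used for
#' inverse-interpolated sampling in the extended walker.
#'
#' @param samples numeric vector with at least 2 distinct values (a single
#'   distinct value yields a flagged degenerate ECDF whose sampler returns
#'   the constant).
#' @param B number of bins (default 100; the grid has `B + 1` abscissae).
#' @return A list of class `bw_ecdf`: `a` (abscissae), `F` (non-decreasing,
#'   `F[1] = 0`, `F[B+1] = 1`), `degenerate`, `n`, `mean`.
#' @export
build_ecdf <- function(samples, B = 100L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 1L) stop("no finite samples")
  rng <- range(samples)
  if (rng[1L] == rng[2L]) {
    return(structure(list(a = rep(rng[1L], 2L), F = c(0, 1),
                          degenerate = TRUE, n = length(samples),
                          mean = rng[1L]),
                     class = "bw_ecdf"))
  }
  if (length(samples) < 2L) stop("need at least 2 distinct samples")
  a <- seq(rng[1L], rng[2L], length.out = B + 1L)
  Fn <- stats::ecdf(samples)
  Fv <- Fn(a)
  Fv[1L] <- 0; Fv[length(Fv)] <- 1
  Fv <- cummax(Fv)
  structure(list(a = a, F = Fv, degenerate = FALSE, n = length(samples),
                 mean = mean(samples)),
            class = "bw_ecdf")
}

#' Inverse-interpolated sampling from a discretised ECDF
#'
#' Draws `r` uniform on \[0, 1), finds the lowest grid abscissa `a_j` with
#' `F(a_j) >= r`, and returns the linear interpolation between `a_{j-1}` and
#' `a_j` proportional to `(r - F(a_{j-1})) / (F(a_j) - F(a_{j-1}))`; `r = 0`
#' returns `a_0`.
#'
#' @param F a [build_ecdf()] object.
#' @param n number of draws.
#' @return Numeric vector of samples on `[a_0, a_B]`.
#' @export
sample_ecdf <- function(F, n = 1L) {
  stopifnot(inherits(F, "bw_ecdf"))
  if (isTRUE(F$degenerate)) return(rep(F$a[1L], n))
  r <- runif(n)
  j <- findInterval(r, F$F, left.open = TRUE) + 1L  # lowest j with F[j] >= r
  j[j < 2L] <- 2L
  lo <- F$F[j - 1L]; hi <- F$F[j]
  out <- F$a[j - 1L] + (r - lo) / (hi - lo) * (F$a[j] - F$a[j - 1L])
  out[r <= F$F[1L]] <- F$a[1L]
  out
}

#' Per-sector motion statistics of segmented trajectories
#'
#' Pools segments from one or more segmented trajectories and estimates, for
#' each heading sector: the mean speed `v_s` (segment length / duration),
#' the mean free path `lambda_s` (arithmetic mean segment length), the
#' persistence `g_s` (mean cosine of deviations), the heading frequency
#' `p_s` (segment-count fraction), and discretised ECDFs of segment lengths
#' and signed deviations. A segment contributes its length and speed to the
#' sector of its own heading; a deviation contributes to the sector of the
#' pre-turn heading (the sector the extended walker draws both quantities
#' from at simulation time). Deviation ECDFs are built on signed deviations
#' in (-pi, pi], preserving any left/right asymmetry.
#'
#' @param segmented a `bw_segmented` object or a list of them.
#' @param part a [sector_partition()].
#' @param B ECDF bin count.
#' @return A list of class `bw_sector_stats` with `part`, `table` (a
#'   data.frame with one row per sector: sector, center, n, n_dev, p,
#'   mean_speed, mean_free_path, persistence, empty), `length_ecdf`,
#'   `deviation_ecdf` (lists of [build_ecdf()] objects or `NULL` for empty
#'   sectors), and `global_speed`.
#' @export
estimate_sector_stats <- function(segmented, part = sector_partition(),
                                  B = 100L) {
  if (inherits(segmented, "bw_segmented")) segmented <- list(segmented)
  stopifnot(length(segmented) >= 1L,
            all(vapply(segmented, inherits, TRUE, "bw_segmented")),
            inherits(part, "bw_sectors"))
  segs <- do.call(rbind, lapply(segmented, `[[`, "segments"))
  if (nrow(segs) < 1L) stop("no segments")
  dev <- unlist(lapply(segmented, `[[`, "deviations"))
  # pre-turn headings aligned with deviations, per trajectory
  pre <- unlist(lapply(segmented, function(s) {
    h <- s$segments$heading
    if (length(h) >= 2L) h[-length(h)] else numeric(0)
  }))
  S <- part$S
  s_seg <- sector_of(segs$heading, part)
  s_dev <- if (length(dev)) sector_of(pre, part) else integer(0)
  ok_dur <- segs$duration > 0
  tab <- data.frame(sector = 0:(S - 1L), center = part$centers,
                    n = 0L, n_dev = 0L, p = 0, mean_speed = NA_real_,
                    mean_free_path = NA_real_, persistence = NA_real_,
                    empty = TRUE)
  length_ecdf <- vector("list", S)
  deviation_ecdf <- vector("list", S)
  for (s in 0:(S - 1L)) {
    i <- which(s_seg == s)
    j <- which(s_dev == s)
    tab$n[s + 1L] <- length(i)
    tab$n_dev[s + 1L] <- length(j)
    if (length(i)) {
      tab$mean_free_path[s + 1L] <- mean(segs$length[i])
      ii <- i[ok_dur[i]]
      if (length(ii))
        tab$mean_speed[s + 1L] <- sum(segs$length[ii]) / sum(segs$duration[ii])
      length_ecdf[[s + 1L]] <- build_ecdf(segs$length[i], B)
    }
    if (length(j)) {
      tab$persistence[s + 1L] <- mean(cos(dev[j]))
      deviation_ecdf[[s + 1L]] <- build_ecdf(dev[j], B)
    }
    tab$empty[s + 1L] <- length(i) == 0L || length(j) == 0L
  }
  tab$p <- tab$n / sum(tab$n)
  gsp <- if (any(ok_dur)) sum(segs$length[ok_dur]) / sum(segs$duration[ok_dur])
         else NA_real_
  structure(list(part = part, table = tab, length_ecdf = length_ecdf,
                 deviation_ecdf = deviation_ecdf, global_speed = gsp),
            class = "bw_sector_stats")
}

#' @export
print.bw_sector_stats <- function(x, ...) {
  cat(sprintf("<bw_sector_stats> %d sectors, %d segments\n",
              x$part$S, sum(x$table$n)))
  print(x$table[, c("sector", "n", "p", "mean_speed", "mean_free_path",
                    "persistence")], row.names = FALSE, digits = 4)
  invisible(x)
}

# stack sector ECDFs into the matrices the C++ walkers consume
ecdf_matrices <- function(stats, which = c("length_ecdf", "deviation_ecdf")) {
  which <- match.arg(which)
  es <- stats[[which]]
  if (any(vapply(es, is.null, TRUE)))
    stop("cannot simulate: empty sector(s) ",
         paste(which(vapply(es, is.null, TRUE)) - 1L, collapse = ", "),
         " in ", which)
  m <- max(vapply(es, function(e) length(e$a), 1L))
  pad <- function(v) c(v, rep(v[length(v)], m - length(v)))
  # one sector per column: the C++ walkers index columns contiguously
  list(a = do.call(cbind, lapply(es, function(e) pad(e$a))),
       F = do.call(cbind, lapply(es, function(e) pad(e$F))))
}

#' Simulate an extended Boltzmann Walker trajectory
#'
#' Generates one trajectory of the heading-conditioned walker: at each
#' event, the sector of the current heading selects the empirical length and
#' deviation distributions ([sample_ecdf()] draws), and the walk stops at
#' the first exact exit from the radius-`R` circle. Speed only scales the
#' event time stamps: by default the global mean speed is used
#' (`speed_mode = "global"`, speed having been found isotropic), with a
#' per-sector option.
#'
#' @param stats a [estimate_sector_stats()] object (no reachable sector may
#'   be empty).
#' @param R exit radius (m), default 0.2; `Inf` disables the boundary.
#' @param speed_mode `"global"` or `"sector"`.
#' @param max_events hard event cap.
#' @return A [trajectory()] of turning points with `exited`, `capped`,
#'   `exit_heading` and per-segment `headings` in `meta`.
#' @export
simulate_extended_bw <- function(stats, R = 0.2,
                                 speed_mode = c("global", "sector"),
                                 max_events = 100000L) {
  stopifnot(inherits(stats, "bw_sector_stats"))
  speed_mode <- match.arg(speed_mode)
  L <- ecdf_matrices(stats, "length_ecdf")
  D <- ecdf_matrices(stats, "deviation_ecdf")
  sp <- sector_speeds(stats, speed_mode)
  sim <- cpp_simulate_ext_bw(L$a, L$F, D$a, D$F, sp, stats$part$offset, R,
                             as.integer(max_events))
  tr <- trajectory(sim$x, sim$y, sim$t,
                   meta = list(exited = sim$exited, capped = sim$capped,
                               exit_heading = sim$exit_heading,
                               headings = sim$headings))
  tr$censored <- !sim$exited
  tr
}

sector_speeds <- function(stats, speed_mode) {
  if (speed_mode == "global") {
    if (!is.finite(stats$global_speed) || stats$global_speed <= 0)
      stop("global mean speed unavailable; use speed_mode = 'sector'")
    return(rep(stats$global_speed, stats$part$S))
  }
  sp <- stats$table$mean_speed
  if (any(!is.finite(sp) | sp <= 0))
    stop("per-sector speed unavailable for sector(s) ",
         paste(which(!is.finite(sp) | sp <= 0) - 1L, collapse = ", "))
  sp
}

#' Predicted exit headings of the extended walker
#'
#' Runs `N` independent extended BW walkers from the center of the
#' radius-`R` circle and returns the heading of each exact circle-crossing
#' point (the population-scale dispersal summary).
#'
#' @param stats a [estimate_sector_stats()] object.
#' @param N number of simulated walkers (default 10000).
#' @param R exit radius (m).
#' @param max_events hard event cap per walker (non-exits yield `NA`).
#' @return Numeric vector of `N` exit headings in (-pi, pi] (0 = uphill).
#' @export
predict_exit_headings <- function(stats, N = 10000L, R = 0.2,
                                  max_events = 100000L) {
  stopifnot(inherits(stats, "bw_sector_stats"), N >= 1)
  L <- ecdf_matrices(stats, "length_ecdf")
  D <- ecdf_matrices(stats, "deviation_ecdf")
  cpp_ext_exit_headings(as.integer(N), L$a, L$F, D$a, D$F,
                        stats$part$offset, R, as.integer(max_events))
}

#' Serialise sector statistics
#'
#' Writes `<base>.json` (scalars: sector table, partition, global speed) and
#' `<base>_ecdf.tsv` (long-format ECDF grids: quantity, sector, abscissa,
#' F). [read_sector_stats()] restores the object.
#'
#' @param stats a [estimate_sector_stats()] object.
#' @param base path prefix (without extension).
#' @return `base`, invisibly.
#' @export
write_sector_stats <- function(stats, base) {
  stopifnot(inherits(stats, "bw_sector_stats"))
  jsonlite::write_json(
    list(S = stats$part$S, offset = stats$part$offset,
         global_speed = stats$global_speed, table = stats$table),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  rows <- list()
  for (q in c("length_ecdf", "deviation_ecdf")) {
    for (s in seq_along(stats[[q]])) {
      e <- stats[[q]][[s]]
      if (is.null(e)) next
      rows[[length(rows) + 1L]] <-
        data.frame(quantity = sub("_ecdf$", "", q), sector = s - 1L,
                   a = sprintf("%.17g", e$a), F = sprintf("%.17g", e$F),
                   n = e$n, degenerate = e$degenerate,
                   mean = sprintf("%.17g", e$mean))
    }
  }
  write.table(do.call(rbind, rows), paste0(base, "_ecdf.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(base)
}

#' @rdname write_sector_stats
#' @export
read_sector_stats <- function(base) {
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  grids <- read.table(paste0(base, "_ecdf.tsv"), sep = "\t", header = TRUE)
  part <- sector_partition(hdr$S, hdr$offset)
  mk <- function(q) {
    out <- vector("list", hdr$S)
    for (s in 0:(hdr$S - 1L)) {
      gr <- grids[grids$quantity == q & grids$sector == s, ]
      if (!nrow(gr)) next
      out[[s + 1L]] <- structure(
        list(a = gr$a, F = gr$F, degenerate = gr$degenerate[1L],
             n = gr$n[1L], mean = gr$mean[1L]), class = "bw_ecdf")
    }
    out
  }
  tab <- as.data.frame(hdr$table)
  structure(list(part = part, table = tab, length_ecdf = mk("length"),
                 deviation_ecdf = mk("deviation"),
                 global_speed = hdr$global_speed),
            class = "bw_sector_stats")
}
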