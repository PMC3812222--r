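#' Construct a trajectory object
#'
#' A `bw_trajectory` holds a time-stamped sequence of 2-D positions in meters,
#' together with the recording metadata carried by the per-individual
#' trajectory files (inclination label, colony, temperature, humidity, date,
#' individual index). The shared coordinate convention across the package is:
#' `y` along the steepest line of the inclined plane, positive uphill; `x`
#' horizontal; headings in radians in (-pi, pi] with 0 = uphill, increasing
#' counterclockwise. Units are meters and seconds throughout.
#'
#' @param x,y numeric vectors of coordinates (meters).
#' @param t numeric vector of times (seconds), strictly increasing.
#' @param meta named list of metadata (free-form; the reader fills
#'   `inclination_label`, `colony_label`, `temperature`, `humidity`, `date`,
#'   `individual_index` when available).
#' @param nominal_rate nominal sampling rate in Hz (default 25).
#'
#' @return An object of class `bw_trajectory`: a list with elements `x`, `y`,
#'   `t`, `meta`, `nominal_rate`, and logical flags `censored` (set by
#'   [truncate_exit()]) and `trim_index` (set by [trim_start()]).
#' @seealso [read_trajectory_file()], [trim_start()], [truncate_exit()]
#' @export
trajectory <- function(x, y, t, meta = list(), nominal_rate = 25) {
  x <- as.numeric(x); y <- as.numeric(y); t <- as.numeric(t)
  n <- length(x)
  if (length(y) != n || length(t) != n)
    stop("x, y and t must have the same length")
  if (n < 2L)
    stop("a trajectory needs at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(t)))
    stop("all coordinates and times must be finite")
  if (any(diff(t) <= 0))
    stop("times must be strictly increasing")
  structure(
    list(x = x, y = y, t = t, meta = meta, nominal_rate = nominal_rate,
         censored = NA, trim_index = NA_integer_),
    class = "bw_trajectory")
}

#' @export
print.bw_trajectory <- function(x, ...) {
  dur <- diff(range(x$t))
  cat(sprintf("<bw_trajectory> %d points, %.1f s", length(x$x), dur))
  if (!is.null(x$meta$inclination_label))
    cat(sprintf(", inclination %s", x$meta$inclination_label))
  if (isTRUE(x$censored)) cat(", censored")
  cat("\n")
  invisible(x)
}

#' @export
length.bw_trajectory <- function(x) length(x$x)

# canonical header of the tab-delimited per-individual dialect
.traj_header <- c("inclination", "colony", "temperature", "humidity",
                  "date", "individual", "frame", "time", "x", "y")

#' Read a per-individual trajectory file
#'
#' Reads the tab-delimited trajectory dialect: one header line followed by one
#' row per video frame, with x and y coordinates (meters) in the final two
#' columns and time in seconds in the column named `time` (or, positionally,
#' the third-from-last column). Both the 9- and 10-column layouts are
#' accepted; when the header names the columns they are matched by name, with
#' positional fallback otherwise. Trailing tabs are tolerated.
#'
#' @param path path to a tab-delimited trajectory file.
#' @param nominal_rate nominal sampling rate in Hz.
#' @return A [trajectory()] object with metadata taken from the first data
#'   row.
#' @export
read_trajectory_file <- function(path, nominal_rate = 25) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("trajectory file needs a header and at least 2 data rows: ", path)
  split_row <- function(s) {
    f <- strsplit(s, "\t", fixed = TRUE)[[1L]]
    # tolerate a trailing tab (empty last field)
    while (length(f) && !nzchar(trimws(f[length(f)]))) f <- f[-length(f)]
    trimws(f)
  }
  header <- tolower(split_row(lines[1L]))
  rows <- lapply(lines[-1L], split_row)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in ", path, " (first at data line ",
         which(ncols != ncols[1L])[1L], ")")
  nc <- ncols[1L]
  find_col <- function(pats, fallback) {
    hit <- which(Reduce(`|`, lapply(pats, function(p) grepl(p, header))))
    if (length(hit) >= 1L) hit[1L] else fallback
  }
  ix <- find_col(c("^x"), nc - 1L)
  iy <- find_col(c("^y"), nc)
  it <- find_col(c("time", "^t$"), nc - 2L)
  num_col <- function(i, what) {
    if (is.na(i) || i < 1L || i > nc)
      stop("could not locate the ", what, " column in ", path)
    v <- suppressWarnings(as.numeric(vapply(rows, `[`, "", i)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at line %d of %s", what, bad[1L] + 1L, path))
    v
  }
  x <- num_col(ix, "x coordinate")
  y <- num_col(iy, "y coordinate")
  t <- num_col(it, "time")
  grab <- function(pats, fallback) {
    i <- find_col(pats, fallback)
    if (is.na(i) || i < 1L || i > nc) NA_character_ else rows[[1L]][i]
  }
  meta <- list(
    inclination_label = grab("inclin", 1L),
    colony_label      = grab("colon", 2L),
    temperature       = suppressWarnings(as.numeric(grab("temp", 3L))),
    humidity          = suppressWarnings(as.numeric(grab("humid", 4L))),
    date              = grab("date", 5L),
    individual_index  = grab(c("individual", "^ant"), 6L),
    source_file       = path)
  trajectory(x, y, t, meta = meta, nominal_rate = nominal_rate)
}

#' Write a trajectory file (with optional JSON sidecar)
#'
#' Writes the same tab-delimited dialect read by [read_trajectory_file()]
#' (10 named columns, coordinates at 12 significant digits) and, optionally, a
#' `<path>.json` sidecar holding the preprocessing flags (`censored`,
#' `trim_index`).
#'
#' @param traj a [trajectory()] object.
#' @param path output file path.
#' @param sidecar write the JSON metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_trajectory_file <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "bw_trajectory"))
  m <- traj$meta
  val <- function(v, d) if (is.null(v) || (length(v) == 1 && is.na(v))) d else v
  n <- length(traj$x)
  fmt <- function(v) sprintf("%.12g", v)
  body <- paste(
    rep(val(m$inclination_label, "NA"), n), rep(val(m$colony_label, "NA"), n),
    rep(fmt(val(m$temperature, NA_real_)), n),
    rep(fmt(val(m$humidity, NA_real_)), n),
    rep(val(m$date, "NA"), n), rep(val(m$individual_index, "NA"), n),
    seq_len(n), fmt(traj$t), fmt(traj$x), fmt(traj$y), sep = "\t")
  writeLines(c(paste(.traj_header, collapse = "\t"), body), path)
  if (sidecar) {
    jsonlite::write_json(
      list(censored = traj$censored, trim_index = traj$trim_index,
           n_points = n),
      paste0(path, ".json"), auto_unbox = TRUE, null = "null", na = "null")
  }
  invisible(path)
}

#' Discard the settling-in start of a trajectory
#'
#' Returns the suffix starting at the first point whose Euclidean distance
#' from the first tracked point (the dropping site) is at least `d`. The
#' dropping site is retained in `meta$origin` for later reference (the exit
#' circle stays centered on it).
#'
#' @param traj a [trajectory()] object.
#' @param d trim distance in meters (default 0.01, i.e. 1 cm).
#' @return The trimmed trajectory; errors if no point ever reaches distance
#'   `d` from the start.
#' @export
trim_start <- function(traj, d = 0.01) {
  stopifnot(inherits(traj, "bw_trajectory"), d > 0)
  x0 <- if (!is.null(traj$meta$origin)) traj$meta$origin[1L] else traj$x[1L]
  y0 <- if (!is.null(traj$meta$origin)) traj$meta$origin[2L] else traj$y[1L]
  dist <- sqrt((traj$x - x0)^2 + (traj$y - y0)^2)
  k <- which(dist >= d)[1L]
  if (is.na(k))
    stop(sprintf("trajectory never reaches %.3g m from its start", d))
  if (length(traj$x) - k + 1L < 2L)
    stop("trimming leaves fewer than 2 points")
  out <- traj
  out$x <- traj$x[k:length(traj$x)]
  out$y <- traj$y[k:length(traj$y)]
  out$t <- traj$t[k:length(traj$t)]
  out$meta$origin <- c(x0, y0)
  out$trim_index <- k
  out
}

#' Truncate a trajectory at its first exit from a circle
#'
#' Returns the prefix ending at the first sample strictly outside radius `R`
#' from `center`. If the trajectory never leaves the circle the full
#' trajectory is returned with `censored = TRUE` (a flagged outcome, not an
#' error).
#'
#' @param traj a [trajectory()] object.
#' @param R exit radius in meters (default 0.2).
#' @param center circle center `c(x, y)`; defaults to the recorded dropping
#'   site (`meta$origin`) or the first point.
#' @return The truncated trajectory with its `censored` flag set.
#' @export
truncate_exit <- function(traj, R = 0.2, center = NULL) {
  stopifnot(inherits(traj, "bw_trajectory"), R > 0)
  if (is.null(center)) {
    center <- if (!is.null(traj$meta$origin)) traj$meta$origin
              else c(traj$x[1L], traj$y[1L])
  }
  dist <- sqrt((traj$x - center[1L])^2 + (traj$y - center[2L])^2)
  k <- which(dist > R)[1L]
  out <- traj
  if (is.na(k)) {
    out$censored <- TRUE
    return(out)
  }
  keep <- seq_len(k)
  out$x <- traj$x[keep]; out$y <- traj$y[keep]; out$t <- traj$t[keep]
  out$censored <- FALSE
  out$meta$exit_center <- center
  out$meta$exit_radius <- R
  out
}

#' Total path length, duration and mean speed
#'
#' @param traj a [trajectory()] object (at least 2 points).
#' @return A named list `list(length, duration, mean_speed)`: `length` is the
#'   sum of consecutive Euclidean steps (m), `duration` the elapsed time (s),
#'   `mean_speed = length / duration` (stops included).
#' @export
path_length_and_speed <- function(traj) {
  stopifnot(inherits(traj, "bw_trajectory"))
  len <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  dur <- traj$t[length(traj$t)] - traj$t[1L]
  if (dur <= 0) stop("zero duration")
  list(length = len, duration = dur, mean_speed = len / dur)
}

# heading of a displacement under the shared convention:
# 0 = uphill (+y), increasing counterclockwise, range (-pi, pi]
heading_from_xy <- function(dx, dy) {
  h <- atan2(-dx, dy)
  ifelse(h <= -pi, h + 2 * pi, h)
}

# unit vector of a heading (inverse of heading_from_xy)
heading_unit <- function(theta) cbind(-sin(theta), cos(theta))
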