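#' Standard Boltzmann Walker parameters
#'
#' Bundles the three parameters of the standard (isotropic) Boltzmann
#' Walker: constant speed `v` (m/s), mean free path `lambda` (m, the mean of
#' the exponential free-path distribution), and persistence `g` (the mean
#' cosine of the turning deviation, in \[0, 1); 0 = uniform reorientation,
#' near 1 = near-ballistic persistence).
#'
#' @param v speed in m/s, > 0.
#' @param lambda mean free path in meters, > 0.
#' @param g persistence (anisotropy coefficient of the phase function).
#' @return A list of class `bw_params`.
#' @export
bw_params <- function(v, lambda, g) {
  if (!is.finite(v) || v <= 0) stop("v must be > 0")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(g) || g < 0 || g >= 1) stop("g must be in [0, 1)")
  structure(list(v = v, lambda = lambda, g = g), class = "bw_params")
}

#' @export
print.bw_params <- function(x, ...) {
  cat(sprintf(
    "<bw_params> v = %g m/s, lambda = %g m, g = %g (D = %g m^2/s)\n",
    x$v, x$lambda, x$g, diffusion_coefficient(x$v, x$lambda, x$g)))
  invisible(x)
}

#' Eccentricity of the elliptical phase function
#'
#' The elliptical phase function is the polar radius of an ellipse with one
#' focus at the origin, `f(alpha) = sqrt(1 - e^2) / (2 pi (1 - e cos
#' alpha))`. Its mean cosine is `(1 - sqrt(1 - e^2)) / e = g`, inverted in
#' closed form as `e = 2 g / (1 + g^2)`.
#'
#' @param g mean cosine (persistence) in \[0, 1).
#' @return Eccentricity `e` in \[0, 1).
#' @export
eccentricity_from_g <- function(g) {
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1))
    stop("g must be in [0, 1)")
  2 * g / (1 + g^2)
}

#' Elliptical phase function density
#'
#' @param alpha deviation angles (radians).
#' @param g mean cosine in \[0, 1).
#' @return Density values of `f(alpha) = sqrt(1 - e^2) / (2 pi (1 - e cos
#'   alpha))` with `e = eccentricity_from_g(g)`.
#' @export
elliptical_pdf <- function(alpha, g) {
  e <- eccentricity_from_g(g)
  sqrt(1 - e^2) / (2 * pi * (1 - e * cos(alpha)))
}

#' Sample turning deviations from the elliptical phase function
#'
#' Exact inverse-CDF sampling: the CDF of the focus-polar elliptical density
#' inverts in closed form to
#' `alpha = 2 atan( sqrt((1 - e)/(1 + e)) tan(pi (r - 1/2)) )`.
#' The distribution is symmetric about 0 with mean cosine exactly `g`.
#'
#' @param n number of draws.
#' @param g mean cosine in \[0, 1).
#' @return Numeric vector of deviations in (-pi, pi].
#' @export
sample_elliptical <- function(n, g) {
  if (length(g) != 1L) stop("g must be scalar")
  if (g == 0) return(runif(n, -pi, pi))
  e <- eccentricity_from_g(g)
  r <- runif(n)
  2 * atan(sqrt((1 - e) / (1 + e)) * tan(pi * (r - 0.5)))
}

#' Sample exponential free-path lengths
#'
#' The memory-less reorientation process makes free paths exponential with
#' survival `P(L > l) = exp(-l / lambda)`.
#'
#' @param n number of draws.
#' @param lambda mean free path (m), > 0.
#' @return Numeric vector of lengths.
#' @export
sample_free_path <- function(n, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  rexp(n, rate = 1 / lambda)
}

#' Simulate a standard Boltzmann Walker trajectory
#'
#' Generates the sequence of turning points of a standard BW: initial
#' heading uniform on (-pi, pi], free paths exponential with mean `lambda`,
#' deviations from the elliptical phase function with mean cosine `g`,
#' constant speed `v` (event times are cumulative length / v). The walk
#' starts at the origin and stops at the first exit from the radius-`R`
#' circle (the boundary crossing is computed exactly by segment-circle
#' intersection) or after `max_events` events (`R = Inf` disables the
#' boundary so exactly `max_events` free paths are drawn).
#'
#' @param params a [bw_params()] object.
#' @param R exit radius in meters (default 0.2; `Inf` for unbounded).
#' @param max_events hard cap on reorientation events.
#' @return A [trajectory()] of turning points with attributes in `meta`:
#'   `exited`, `capped`, `exit_heading` (angle of the exact circle-crossing
#'   point), `headings` (per-segment headings).
#' @export
simulate_bw <- function(params, R = 0.2, max_events = 100000L) {
  stopifnot(inherits(params, "bw_params"))
  sim <- cpp_simulate_bw(params$v, params$lambda, params$g, R,
                         as.integer(max_events))
  tr <- trajectory(sim$x, sim$y, sim$t,
                   meta = list(exited = sim$exited, capped = sim$capped,
                               exit_heading = sim$exit_heading,
                               headings = sim$headings,
                               params = unclass(params)))
  tr$censored <- !sim$exited
  tr
}

#' Diffusion coefficient of the Boltzmann Walker
#'
#' In 2-D the long-time spreading of a BW population is diffusive with
#' `D = v lambda / (2 (1 - g))`: the diffusion coefficient depends on the
#' mean free path and the phase function only through the transport mean
#' free path `lambda* = lambda / (1 - g)`.
#'
#' @param v speed (m/s).
#' @param lambda mean free path (m).
#' @param g persistence, < 1.
#' @return Diffusion coefficient in m^2/s.
#' @seealso [transport_mean_free_path()]
#' @export
diffusion_coefficient <- function(v, lambda, g) {
  if (any(g >= 1)) stop("D diverges as g -> 1")
  v * lambda / (2 * (1 - g))
}

#' Transport mean free path
#'
#' `lambda* = lambda / (1 - g)`: the mean free path of the pure (g = 0)
#' random walk with the same diffusion coefficient.
#'
#' @inheritParams diffusion_coefficient
#' @return Transport mean free path in meters.
#' @export
transport_mean_free_path <- function(lambda, g) {
  if (any(g >= 1)) stop("transport mean free path diverges as g -> 1")
  lambda / (1 - g)
}

#' Closed-form mean square displacement of a correlated random walk
#'
#' Expected squared displacement after `n` steps with i.i.d. exponential
#' lengths of mean `lambda` and symmetric turning deviations of mean cosine
#' `g` (so that heading correlation decays as `g^k` over k events):
#' \deqn{E[R_n^2] = 2 \lambda^2 \left[ n + \frac{g}{1-g}\left(n -
#'   \frac{1-g^n}{1-g}\right) \right]}
#' Limits: `n = 1` gives `2 lambda^2` (second moment of the exponential),
#' `g = 0` gives `2 n lambda^2`, and the large-`n` slope per event is
#' `2 lambda^2 / (1 - g)`, consistent with `4 D (lambda / v)` per event.
#' Used as the independent oracle for simulated MSD curves.
#'
#' @param n vector of event counts, >= 1.
#' @param lambda mean free path (m).
#' @param g persistence in \[0, 1).
#' @return Expected squared displacement (m^2) for each `n`.
#' @export
crw_msd_oracle <- function(n, lambda, g) {
  if (any(n < 1)) stop("n must be >= 1")
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (g == 0) return(2 * n * lambda^2)
  2 * lambda^2 * (n + g / (1 - g) * (n - (1 - g^n) / (1 - g)))
}

#' Simulated MSD as a function of reorientation events
#'
#' Averages `|X_n|^2` over `n_walkers` independent unbounded standard BWs
#' for `n = 1, ..., n_events`.
#'
#' @param params a [bw_params()] object.
#' @param n_walkers number of independent walkers.
#' @param n_events number of events per walker.
#' @return Numeric vector of length `n_events`.
#' @export
bw_msd_events <- function(params, n_walkers = 1000L, n_events = 50L) {
  stopifnot(inherits(params, "bw_params"))
  cpp_bw_msd_events(params$lambda, params$g, as.integer(n_walkers),
                    as.integer(n_events))
}

#' Simulated MSD as a function of time
#'
#' @param params a [bw_params()] object.
#' @param times times (s) at which squared displacement is recorded
#'   (positions are interpolated within free paths).
#' @param n_walkers number of independent walkers.
#' @return Numeric vector, `MSD(times)`.
#' @export
bw_msd_times <- function(params, times, n_walkers = 1000L) {
  stopifnot(inherits(params, "bw_params"))
  cpp_bw_msd_times(params$v, params$lambda, params$g, as.integer(n_walkers),
                   as.numeric(times))
}
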