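---
title: "Boltzmann Walker analysis of 2-D trajectories: models, estimation, and design choices"
author: "boltzwalker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boltzmann Walker analysis of 2-D trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The Boltzmann Walker (BW) — the *velocity-jump process* of movement
ecology, borrowed from linear transport theory — describes an animal that
walks in a straight line at constant speed $v$ until it instantaneously
reorients, then walks straight again. Two ingredients specify the
stochastic part:

* **Free paths.** Reorientation is memory-less, so the distance $L$ walked
  between consecutive events is exponential,
  $P(L > l) = \exp(-l/\lambda)$, with mean free path $\lambda$ (m).
* **Phase function.** At an event the heading deviates by a random angle
  $\alpha$ drawn from a density $f(\alpha)$ symmetric about 0 (the
  scattering indicatrix). Its mean cosine
  $g = \int \cos\alpha\, f(\alpha)\, d\alpha$ is the persistence
  (anisotropy) coefficient: $g = 0$ is a pure random walk, $g \to 1$ is
  near-ballistic, and negative $g$ would describe a u-turner.

At long times the population spreads diffusively with (in 2-D)
$$D = \frac{v \lambda}{2 (1 - g)},$$
so the observable spreading rate constrains only the *transport mean free
path* $\lambda^* = \lambda / (1 - g)$, not $\lambda$ and $g$ separately.
`diffusion_coefficient()` and `transport_mean_free_path()` expose these,
and `crw_msd_oracle()` gives the exact finite-$n$ mean square displacement
after $n$ events,
$$E[R_n^2] \;=\; 2\lambda^2\!\left[\, n + \frac{g}{1-g}\left(n -
\frac{1-g^n}{1-g}\right)\right],$$
derived from $E[L^2] = 2\lambda^2$ and the $g^{|i-j|}$ decay of heading
correlations (symmetric increments make the sine terms vanish). Its three
limits — $2\lambda^2$ at $n=1$, $2n\lambda^2$ at $g=0$, slope
$2\lambda^2/(1-g)$ per event at large $n$, i.e. $4D\,(\lambda/v)$ per event
— anchor the simulation tests.

The **extended** BW lets all three parameters depend on the current heading
$\theta$ relative to an external directional field (here: the slope of the
inclined plane). It is the package's device for quantifying how a walker
reacts to gravity: klinokinesis (heading-dependent $\lambda$), orthokinesis
(heading-dependent $v$), and taxis (heading-dependent turning).

### Conventions

All modules share one frame: $y$ along the steepest line, positive uphill;
$x$ horizontal; headings in radians in $(-\pi, \pi]$ with $0$ = uphill,
increasing counterclockwise (so $-\pi/2$ points along $+x$). Units are
meters and seconds everywhere. Angles are wrapped by `wrap_angle()` with
the boundary convention $-\pi \mapsto \pi$.

## The elliptical phase function

Artificial data need a concrete $f$. We use the focus-polar radius of an
ellipse,
$$f(\alpha) = \frac{\sqrt{1 - e^2}}{2\pi\,(1 - e \cos\alpha)}, \qquad
e = \frac{2g}{1+g^2},$$
whose mean cosine is exactly $(1 - \sqrt{1-e^2})/e = g$. The CDF inverts in
closed form, so `sample_elliptical()` is an exact inverse-CDF sampler:
$\alpha = 2\arctan\!\big(\sqrt{(1-e)/(1+e)}\, \tan \pi(r - \tfrac12)\big)$
for $r$ uniform. The published listing of the sampling algorithm is not
available to us; any faithful alternative must satisfy the same testable
contract, $E[\cos\alpha] = g$, which our tests assert on a grid of $g$
together with the unit normalisation and the symmetry $E[\sin\alpha] = 0$.
Negative $g$ is excluded from the elliptical family; arbitrary (including
u-turning) shapes enter through the empirical distributions of the extended
walker instead.

## Segmentation: from noisy points to free paths

Tracked data are a 25 Hz point series, not a polyline of turning points.
`segment_trajectory()` recovers the free paths by **bottom-up
piecewise-linear segmentation**:

1. Start from the finest partition: one segment per pair of consecutive
   points (total error zero).
2. Score two kinds of candidate moves — a *pair merge* (two adjacent
   segments → one) and a *triple merge* (three adjacent segments → two,
   split at the interior point that minimises the error). A candidate's
   cost is the refitted maximum point-to-axis distance of the new
   segment(s).
3. Apply the cheapest candidate; stop when no candidate stays within the
   accepted criterion $\varepsilon$.

A segment is fitted as the principal axis of its point cloud through the
centroid; its endpoints are the orthogonal projections of the first and
last member points, and the error is measured to the *infinite* axis line
(matching the projection construction). Eigenvalue ties break toward the
first-to-last chord; equal-cost candidates prefer the pair merge, then the
lowest index — both for determinism. After a merge only candidates
touching the changed segments are re-scored (a lazy priority queue), which
keeps a 38,000-point trajectory around a second in the compiled
implementation. At termination every point is within $\varepsilon$ of its
segment's axis, and no remaining pair merge is admissible — both properties
are asserted post hoc in the tests, and on series of up to 12 points an
exhaustive search over all breakpoint subsets confirms that the greedy
result is a valid partition whose size is never below the optimum.

Turning angles between consecutive fitted segments are the smallest signed
deviations $\alpha_i = ((\theta_{i+1} - \theta_i + \pi) \bmod 2\pi) - \pi$.
Because adjacent fitted segments project a shared boundary *data point*
onto two different axes, their endpoints agree only to within
$\varepsilon$; reorientation locations (for MSD) therefore use the shared
boundary data points themselves.

### Choosing the criterion $\varepsilon$

$\varepsilon$ (m) is the single tuning parameter that matters, and it is a
*minimal resolvable turning angle* in disguise: merging two segments of
lengths $l_1, l_2$ meeting at angle $\alpha$ leaves a corner at height
$\approx |\sin\alpha| \, l_1 l_2 / (l_1 + l_2)$ above the merged line, so
corners below roughly $\alpha_{\min} \sim \varepsilon (l_1+l_2)/(l_1 l_2)$
are invisible. Three regimes matter:

* **Below the noise floor** ($\varepsilon \lesssim 2\text{--}3\sigma$ for
  tracking noise of SD $\sigma$ per coordinate): noise wiggles spawn
  spurious segments, the segment count explodes and $\hat\lambda$
  collapses. The shipped default $\varepsilon = 6 \times 10^{-4}$ m is
  $3\sigma$ at the calibrated noise $\sigma = 2 \times 10^{-4}$ m, chosen
  so that sub-noise wiggles never spawn segments.
* **Demanding** (noise-free synthetic data): only geometry limits
  resolution. On a walk with $\lambda = 0.01$ m, $g = 0.6$, resampled at
  spacing $\lambda/16.7$, a criterion of spacing/4 recovers about 2037 of
  2266 true segments — the package's reference benchmark
  (`reproduce_paper_validation()`), reproduced within $\pm 5\%$ across
  seeds by `scripts/acceptance.R`. The missed corners are exactly those
  below the resolvable angle: small $|\alpha|$, plus the rarer
  near-reversals ($|\alpha| \approx \pi$), which no collinearity criterion
  can see because a u-turn retraces its own line. Dropping those ~10% of
  (mostly tiny) corners shifts the recovered length and deviation
  distributions slightly (KS gap below 0.1 against the generator's),
  biases $\hat\lambda$ up and $\hat g$ down.
* **Fair estimation**: a slightly stricter criterion (spacing/5 on
  noise-free data) balances corner-merging against corner-splitting so
  that both $\hat\lambda$ (within 10%) and $\hat g$ (within 0.05) are
  recovered across a grid of true $\lambda$ — the default of
  `recovery_experiment()`. With noise present the same trade-off
  re-appears around $\varepsilon \approx 2.25\sigma$, where the
  noise-splitting and corner-merging biases cancel; `recovery_experiment(
  lambda, sigma = 2e-4, epsilon = ...)` reproduces that scan.

We considered a single criterion for both synthetic uses but the two
printed constraints (benchmark count; fair joint recovery) pin slightly
different values under our max-error fit, so each use carries its own
calibrated default, exposed as arguments. Since the criterion is
ultimately an angle at fixed sampling rate, it scales with point spacing
and hence speed: `scale_criterion()` applies the linear rule
$\varepsilon = \varepsilon_0 \, \bar v / v_{\mathrm{ref}}$ for recordings
slower than the reference (e.g. steeper inclines).

## Axial circular statistics

Headings on a slope are typically *axial*: up and down are both common, so
$\theta$ and $\theta + \pi$ must be treated as one orientation. Following
the standard angle-doubling construction, `axial_stats()` doubles the
angles, reduces modulo $2\pi$, computes the mean vector
$(\bar X, \bar Y)$, the mean resultant length
$\bar R = \sqrt{\bar X^2 + \bar Y^2}$ and mean angle
$\phi^* = \operatorname{atan2}(\bar Y, \bar X)$, and back-transforms: mean
axis $\bar\phi = \phi^*/2 \in [0, \pi)$ and axial angular deviation
$s = \tfrac12 \sqrt{2 (1 - \bar R)}$ (the doubled-sample deviation halved —
the exact published form of the back-transformation is not available to
us, so the standard one is used and documented here).

`hodges_ajne()` tests circular uniformity via $m$, the minimum number of
points in any closed half-plane, swept over the $n$ data diameters. The
p-value is exact, $2^{1-n}(n - 2m)\binom{n}{m}$, for $n \le 50$ and uses
the large-sample approximation
$A = \pi\sqrt{n} / (2(n-2m))$,
$p = \sqrt{2\pi}\,A^{-1} e^{-\pi^2/(8A^2)}$ above (avoiding factorial
overflow). One design decision deserves emphasis: **the test is applied to
doubled angles by default** (`axial = TRUE`). Any antipodally symmetric
density — e.g. a balanced up/down bimodal — puts exactly half its mass in
every half-plane, so the raw statistic sits at $m \approx n/2$ and the
test has no power at all against the alternatives this package most cares
about; doubling folds opposite modes together and restores power (we
measured power 1.0 versus 0.025 on balanced opposite von-Mises modes,
$\kappa = 2$, $n = 200$), while uniform data stay uniform under doubling,
so the type-I level is untouched. Raw-angle behaviour remains available
via `axial = FALSE`.

`local_headings()` supplies the model-free view used for display
statistics: non-overlapping 1-s windows, each summarised by the
orientation of the first principal axis of its point cloud (axial, in
$[0, \pi)$), with degenerate windows skipped and counted.

## The extended walker: estimation and simulation

`estimate_sector_stats()` partitions pooled segments into $S = 8$ half-open
heading sectors of width $2\pi/S$, sector 0 centred uphill (16 sectors are
conventional for display histograms only). Conditioning follows the
simulation loop exactly: a segment's length and speed belong to the sector
of *its own* heading; a turning deviation belongs to the sector of the
*pre-turn* heading — because the simulated walker, standing at an event
with heading $\theta$, draws both its next free path and its deviation
from the sector of $\theta$. Deviation distributions keep their sign
(left/right asymmetries are preserved; no symmetrisation), and the
estimates inherit the mirror symmetry of the data: reflecting all headings
about the vertical axis relabels the sectors and negates the deviation
distributions, which the tests assert exactly.

Each sector's length and deviation samples are stored as an empirical CDF
discretised on a uniform 100-bin abscissa grid with endpoints forced to
$F(a_0) = 0$ and $F(a_B) = 1$ (accepting a vanishing bias at the lower
edge). Sampling inverts the grid by linear interpolation: draw $r$ uniform,
find the lowest $a_j$ with $F(a_j) \ge r$, return
$a_{j-1} + (r - F(a_{j-1}))/(F(a_j) - F(a_{j-1})) \cdot (a_j - a_{j-1})$.
A sector with a single distinct value yields a flagged degenerate ECDF
whose sampler returns the constant; an *empty* sector makes simulation
refuse to run (the estimate cannot say what the walker would do there).

`simulate_extended_bw()` then iterates: sector of current heading → ECDF
draw of the free path → advance (with exact segment-circle intersection at
the radius-$R$ boundary, default $R = 0.2$ m) → ECDF draw of the deviation
→ turn. Speed only scales time stamps; because observed speed is isotropic
the default is the global mean (`speed_mode = "global"`), with a per-sector
option. `predict_exit_headings()` repeats this from the centre and records
the angle of each exact circle crossing — the population-scale dispersal
summary compared against observed exit headings with the two-sample KS
test (`ks_two_sample()`; note the linear KS test on a circular support
ignores the wrap-around — kept deliberately for comparability, and
documented as questionable for circular data).

One practical caveat: sector statistics estimated from a *finite* sample
are never exactly isotropic, and with very large simulation counts ($N$ in
the tens of thousands) a uniformity test on predicted exit headings will
eventually detect that estimation noise. Comparisons should either match
$N$ to the precision of the estimate or rely on the observed-vs-predicted
KS comparison, which accounts for the observed sample size.

## What the synthetic generator does and does not emulate

Synthetic "ants" are produced by `simulate_bw()` (or the extended
simulator) → `resample_constant_rate()` → `add_tracking_noise()`:
constant-speed straight paths, exponential free paths, elliptical turning
at $g = 0.6$ and $\lambda = 0.01$ m (ant-like defaults), resampled at 25 Hz
(spacing $v \,dt$, corners crossed rather than snapped, trailing partial
interval dropped) with i.i.d. Gaussian tracking noise of SD
$2 \times 10^{-4}$ m per coordinate (sub-millimeter precision; the real
noise model is unpublished, so isotropic i.i.d. Gaussian is the stated
choice). The generator deliberately omits: stops and speed fluctuations
within a trajectory, autocorrelated or heteroscedastic tracking error,
finite-arena edge effects, and any inter-individual variability. A green
test therefore establishes that the estimators invert the generative model
they assume — not that real ants satisfy that model; the residence-time
and MSD diagnostics are the places where violations of the assumptions
would surface on real data.

## Numerical choices

* Randomness: all compiled samplers draw from R's own generator, so a
  single `set.seed()` governs everything; the pipeline derives
  deterministic per-group sub-seeds from its master seed and a rerun is
  byte-identical.
* Angles wrap to $(-\pi, \pi]$ with $-\pi \mapsto \pi$; sector arcs are
  half-open $[c - \pi/S, c + \pi/S)$.
* Boundary crossings solve the segment-circle quadratic explicitly; exit
  points sit on the circle to $10^{-12}$ m.
* Degenerate inputs error early and explicitly: identical points in
  `fit_segment()`, zero duration in `path_length_and_speed()`, a
  trajectory that never reaches the trim distance, $g \ge 1$ in the
  diffusion formulas.
* The per-ant file dialect is tab-delimited with one header line; both the
  9- and 10-column layouts are accepted, matched by header names with
  positional fallback (the published column enumeration is internally
  inconsistent), and trailing tabs are tolerated. Coordinates are written
  at 12 significant digits so a write-read round trip is lossless at
  analysis precision.

## Known limitations

* $\hat\lambda$ and $\hat g$ are biased wherever the criterion cannot
  resolve small corners; the bias is quantified and the calibrated
  criteria minimise it, but it does not vanish.
* The linear KS test on exit headings ignores circular wrap-around.
* The greedy segmentation is a heuristic: it guarantees validity and local
  maximality, not global optimality (the exhaustive oracle covers only
  tiny series).
* Position-dependent parameters (heterogeneous landscapes) and numerical
  solution of the transport equation are out of scope; the diffusion
  formulas appear only as asymptotic checks.
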