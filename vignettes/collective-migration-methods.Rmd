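---
title: "Models and methods: active Voronoi sheets and collective-migration statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: active Voronoi sheets and collective-migration statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spvflock)
```

`spvflock` reconstructs the computational machinery used to characterise
serum-induced collective migration in confluent keratinocyte sheets: a hybrid
active-Voronoi/Vicsek tissue simulator, the velocity-field and cell-track
statistics applied to time-lapse imaging (order parameters, the 5-sigma
correlation length, fixed-lag MSD, the migration persistency index, circular
division-direction statistics, relative nuclear positioning), and a binomial
model of asymmetric organelle inheritance. Because the underlying microscopy
data are not deposited, every input class has a seeded synthetic generator,
and the whole pipeline is exercised end to end on synthetic data.

## The tissue model

Cells are the Voronoi regions of `N` generating points in a periodic square
box of side `L = sqrt(N * A0)`, so the tessellation is confluent by
construction and the mean cell area is exactly the preferred area `A0`.
The tissue energy is the standard double-quadratic shape functional

$$E = \sum_{j=1}^{N} K_A (A_j - A_0)^2 + K_p (p_j - p_0)^2,$$

penalising deviations of each cell's area \(A_j\) (volume incompressibility
and resistance to height fluctuation) and perimeter \(p_j\) (cortical
contractility balanced against cell–cell adhesion). Positions obey the
overdamped equation of motion

$$\mathbf{r}_i(t+\Delta t) = \mathbf{r}_i(t) +
  \left[\mu \mathbf{F}_i(t) + v_0\, \mathbf{n}_i(t+\Delta t)\right]\Delta t,
  \qquad \mathbf{F}_i = -\nabla_i E,$$

with mobility \(\mu\), self-propulsion speed \(v_0\) along the polarization
\(\mathbf{n}_i = (\cos\theta_i, \sin\theta_i)\). The polarization angle
follows a Vicsek-type alignment rule,

$$\theta_i(t+\Delta t) = \theta_i(t) + \frac{\Delta t}{\tau_V}
  \left\langle \phi_j - \theta_i \right\rangle_{0 < |\mathbf{r}_j -
  \mathbf{r}_i| \le R_V} + \eta_i(t),$$

where \(\phi_j\) is the direction of neighbour \(j\)'s displacement over the
previous step, the average runs over all cells within the Vicsek radius
\(R_V\) (centre-to-centre, minimum image — `R_V` may exceed the first
neighbour shell, so Voronoi adjacency would be the wrong neighbourhood), and
\(\eta_i\) is rotational noise. `R_V` is the model's proxy for
calcium-dependent cell–cell connectivity: `R_V = 0` disconnects the cells,
large `R_V` couples each cell's polarization to many neighbours' motion.

Lengths are measured in `r0 = sqrt(A0)` and times in
`tau0 = 1/(mu K_A A0)`. The default parameter set is `N = 1000`,
`K_A = K_p = mu = 1`, `v0 = 0.5`, `tau_V = 1`, `D_r = 1.5`, `dt = 0.001`,
and shape index `p0/sqrt(A0) = 4.0` (a fluid-like tissue; the rigidity
transition of this model family sits near 3.81). The simulation protocol is
10,000 passive equilibration steps (`v0 = R_V = 0`) from uniformly random
positions and polarizations, then 20,000 production steps with activity on.

### Numerical choices

* **Noise discretization.** The alignment noise is stated as zero-mean with
  variance `2 D_r` without reference to the step size. We use the standard
  Brownian-rotation discretization: a Gaussian increment of variance
  `2 D_r dt` per step, which makes the angular dynamics independent of `dt`.
  This choice matters: a literal per-step variance of `2 D_r` at
  `dt = 0.001` decorrelates the polarization within a step or two and
  collapses the mean speed by a factor of about five, incompatible with the
  reported speed scale.
* **Circular averaging.** Each difference \(\phi_j - \theta_i\) is wrapped
  into \((-\pi, \pi]\) before the arithmetic mean; a plain average of raw
  angle differences is ill-defined on the circle. Cells whose previous
  displacement is exactly zero have no velocity direction and are skipped;
  an empty neighbourhood contributes no alignment term. On the first step
  (no previous displacements) the alignment term is zero.
* **Update order.** Angles are updated first, using displacements of the
  completed previous step; positions then advance with the *new*
  polarization, matching the time indices of the equations above.
* **Geometry.** Each cell's Voronoi polygon is built by clipping a large
  square with perpendicular bisectors of nearby generators (periodic images
  included), processed nearest-first. Clipping stops once the next candidate
  is farther than twice the current maximal vertex radius; if the final
  polygon does not satisfy that same bound against the search radius, the
  search radius is doubled and the cell rebuilt, so the polygon is always
  exact. Degenerate (cocircular) vertex pairs closer than `1e-10 r0` are
  merged; the associated zero-length edge is dropped.
* **Forces.** \(\mathbf{F}_i = -\nabla_i E\) is evaluated analytically:
  every polygon vertex is the circumcenter of the triple of generators
  formed by the cell and the owners of the two adjacent polygon edges, and
  the chain rule is taken through the circumcenter coordinates. The test
  suite checks the gradient against central finite differences of the
  energy (relative error below `1e-5` required; about `1e-9` observed) and
  checks that forces sum to zero (translation invariance) and that areas
  tile the box exactly.
* **Energy descent.** With `v0 = 0` and `dt = 0.001` the explicit Euler
  update is strictly dissipative from moderately disordered states
  (perturbed lattices). From extreme Poisson-random configurations, where
  near-degenerate cells produce forces of order 10–20 energy/length, single
  Euler steps can overshoot kinks of the piecewise-smooth energy landscape
  and transiently raise `E`; this is a property of explicit integration at
  fixed `dt`, not of the gradient, and disappears once the configuration has
  relaxed for a few dozen steps.

### Observables

Mean cell speed uses lagged displacements,
\(v_i(t) = |\mathbf{r}_i(t + 100\Delta t) - \mathbf{r}_i(t)| / (100\Delta t)\),
averaged over cells, with positions unwrapped across the periodic boundary.
The instantaneous order parameter (IOP) is the magnitude of the mean
unit-velocity vector over cells with speed above `1e-9 r0/tau0`; it is 1 for
perfectly aligned motion and of order \(N^{-1/2}\) for disordered motion.
Observables are recorded every 100 steps (matching the speed lag) and
steady-state means are taken over the final half of production.

With the default parameters the model reproduces the published behaviour
pattern: a passive sheet (`v0 = 0`) is essentially static; activity alone
(`R_V = 0`) yields a finite steady speed with negligible order; increasing
`R_V` leaves the speed nearly unchanged but drives the IOP up monotonically
(flocking). At `N = 256` and `N = 1000` the steady speed agrees to better
than 1%, so the reduced size is used for routine runs. Our steady speed at
the default parameters is approximately 0.31 `r0/tau0` — inside the
published sweep range (0.26–0.32) though somewhat above the rounded 0.25
quoted for the radius-zero case; the discrepancy is insensitive to system
size, seed, and steady-state window, and is discussed in the test suite's
acceptance checks, which assert the published tolerance as stated.

## Velocity-field statistics

`velocity_field` holds the U/V component rasters of one PIV frame with a
validity mask and the physical window spacing; masked windows are excluded
from every statistic. `temporal_median` (pixelwise median of 3 consecutive
frames) mirrors the pre-processing used to suppress free-floating debris,
and `speed_field` computes `M = sqrt(U^2 + V^2)` with a mask-aware 5x5
spatial median.

The angle–distance correlation curve follows the published algorithm
exactly: the vectors on the main diagonal act as seeds; from each seed the
four cardinal directions are walked one window at a time; at each integer
distance the angle between seed and target vector is recorded (masked,
out-of-range and zero-magnitude positions are skipped); and angles are
averaged per distance. The 5-sigma correlation length is

$$C_{vv} = \max r \;:\; \overline{\theta}(r) + 5\,\mathrm{SEM}(\theta(r)) < 90^\circ ,$$

the largest distance at which vectors still point within 90 degrees of each
other on average, with 5-sigma confidence (`sigma_tail_prob(5)` is about
3e-7). Distances with fewer than two samples are ineligible. Two readings of
"largest distance" are possible when an intermediate distance fails while a
larger one passes; the default takes the maximum passing distance (the
published formula is a maximum over `r`), and `contiguous = TRUE` provides
the stop-at-first-failure variant for sensitivity analysis. The SEM
denominator is the number of angle samples collected at that distance
(seeds x directions, after skipping); the source text does not pin this
down, and the choice is recorded here. `allpairs_correlation_oracle` is an
exhaustive all-pairs estimator used as an independent reference on small
grids.

## Track statistics

* `fixed_lag_msd` implements the fixed-lag (5 h) mean square displacement:
  for each time point, the squared displacement between `t` and `t + lag`
  averaged over tracks spanning both times; tracks shorter than 19 spots are
  discarded, and the lag must be an exact multiple of the frame interval
  (tracks are never interpolated).
* `mpi_series` is the migration persistency index: within a running window
  of 10 frames, the unit vectors of consecutive displacements are averaged
  and the MPI is the magnitude of that mean — 1 for straight-line motion,
  about 0.28 for independent random headings (window 10), exactly `1/9` for
  a perfectly alternating track. Zero-length displacements have no direction
  and are skipped; the divisor is the number of retained vectors.
* `direction_order_stats` treats each division (or nucleus-to-Golgi) angle
  as a unit vector and reports component means, the resultant magnitude
  `||<d>||` (1 = fully aligned, 0 = no common direction) and the mean angle
  via the two-argument arctangent (the printed `arctan(<y>/<x>)` is
  ambiguous across quadrants). Directed statistics are the default because
  prophase polarity defines a direction; axial mode (angle doubling) is
  available for the orientation-axis reading.
* `relative_nuclear_position` computes `p = |c - x| / |y - x|` from nucleus
  centre and membrane points, aligned so time 0 is the last frame before
  mitosis entry, matching reversed traversal of the time lapse.

## The binomial inheritance model

Each division deposits `n` cytoplasmic PML/nucleoporin bodies (CyPNs), and
each body lands in one fixed daughter independently with probability
`p_sym`; complete asymmetry (all bodies in one daughter) then has
probability

$$P(\text{complete} \mid n) = p_{\mathrm{sym}}^{\,n} + (1-p_{\mathrm{sym}})^{\,n},$$

which is `2^(1-n)` at the unbiased point `p_sym = 0.5` and decreasing in
`n`. The alternative reading of a "binomial" model — a fixed per-division
probability of a symmetric outcome — cannot produce an `n`-dependent curve
and is rejected. `fit_psym` maximises the Bernoulli likelihood of the
complete/incomplete indicator given each division's total; the likelihood is
symmetric under `p -> 1 - p` and the branch `p <= 0.5` is reported. At
`p_sym = 0.5` the curve is stationary in `p`, the Fisher information
vanishes, and the estimator converges at a slower-than-`sqrt(n)` rate — the
test suite therefore asserts a wider recovery band at the symmetric point
than elsewhere. `asym_excess_test` is a Monte-Carlo test of excess complete
asymmetry: the null count is resampled from the per-division probabilities
(grouped by total, as independent binomials) and the exceedance probability
uses an add-one correction. Because the count statistic is discrete, the
attainable level of the test approaches the nominal 0.05 only for datasets
of a few hundred divisions; the calibration test uses 400.

Divisions with zero total bodies are excluded from both the observed
asymmetry fraction and the fit (an undetectable outcome). The per-division
CyPN-count distribution is not published; the generator's default count law
is uniform on 1..6, which is a placeholder for testing the machinery, not a
claim about the data.

## Synthetic data

The generators emulate the five input classes consumed by the analytics, as
pure functions of their seed:

* `gen_gridded_flow` — PIV-like vector fields with deterministic magnitude
  and an angle field of tunable spatial order. Smoothing acts on the unit
  heading components, not raw angles, to avoid wrap-around artefacts, and
  vectors are re-normalised afterwards; the correlation length recovered by
  the analytics increases monotonically with the smoothing scale.
* `gen_vicsek_particles` — the classic point-particle Vicsek model (mean
  neighbour heading within a radius plus uniform noise), rasterized by
  per-window velocity averaging with empty windows masked; an order-tunable
  flow source that reduces to full alignment under noiseless global
  coupling.
* `gen_tracks` — ballistic, persistent (wrapped-normal turning with SD
  `(1 - persistence) * 180` degrees: simple, monotone, bounded), Brownian,
  alternating, and stationary tracks with known closed-form statistics.
  Each track draws from its own substream (a sub-seed drawn from the spec
  seed), so a track's path does not depend on how many tracks precede it.
* `gen_division_angles` — von Mises directions (Best–Fisher sampler;
  concentration 0 is uniform).
* `gen_inheritance_counts` — daughter-pair counts under the partitioning
  model above.
* `gen_premitotic_track` — nucleus/membrane coordinate triplets with a
  stationary jittered phase followed by a linear drift towards the near
  membrane point during the final `drift_onset` minutes (default 30,
  matching the observed onset of active pre-mitotic nuclear movement).

What the generators deliberately do not emulate: PIV window
cross-correlation noise, segmentation errors, drift, division and apoptosis
within tracks, and spatially heterogeneous activation. Tests passing on
synthetic data therefore validate the *statistics machinery* — estimator
identities, invariances, limits and calibration — not the biological
conclusions drawn from real movies.

## Problem sizes and reproducibility

Routine simulation checks run at `N = 256` cells (the steady speed is
size-insensitive; see above), with the published 10,000 + 20,000 step
protocol and 3 seeded runs per condition; `rv_sweep` spans
`R_V = 0 ... 10`. Statistical calibration tests use 500 synthetic datasets
of 400 divisions (type-I error), 1e4 divisions (parameter recovery), and 20
replicate fields (estimator agreement). Every stochastic component takes an
explicit integer seed, and identical seeds reproduce results bit for bit.

`scripts/acceptance.R` re-runs the Vicsek-radius sweep from scratch at these
sizes and writes the steady-state speed at `R_V = 0`, the minimum and
maximum steady speeds across the active sweep, and the MPI of a ballistic
track, as JSON.

## Known limitations

* The simulator is two-dimensional, has fixed cell number (no division or
  apoptosis), and uses a single Euler integrator at the published `dt`.
* The alignment noise convention (variance `2 D_r dt` per step) is a
  documented reconstruction; with it, the radius-zero steady speed computes
  to ~0.31 `r0/tau0` rather than the quoted ~0.25 (see above).
* The correlation-length SEM convention and the contiguity question admit
  two readings each; both are implemented, defaults documented above.
* Quantities tied to the unavailable microscopy data (absolute speeds in
  um/h, millimetre correlation lengths, observed asymmetry percentages and
  their best-fit `p_sym` values) are outside what synthetic data can
  certify.
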