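---
title: "Methods: movement models, foraging areas and habitat suitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement models, foraging areas and habitat suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `urbanraptor`, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic-data generators do and do not establish.

## Working projection and geometry

All distances and areas are computed in a single local metric projection: a
spherical transverse Mercator centred on the study region (default: the
data centroid).  At city scale (≲ 30 km from the central meridian) the scale
distortion is below 10⁻⁴, negligible against every tolerance used here, and
the forward/inverse pair is closed-form, so coordinates round-trip to
machine precision.  Point-in-polygon tests use ray casting with boundary
points counted inside (a deterministic tie-break); polygon areas use the
shoelace formula.

## Track quality control

Fixes with HDOP > 4 or fewer than 5 satellites are dropped — the boundary
values are kept, matching the strict inequalities of the rule.  The daylight
filter retains fixes whose geometric solar elevation at the fix's own
coordinates and time is ≥ −12° (daytime including nautical twilight).
Refraction is ignored: it moves the −12° crossing by < 0.6°, immaterial at
5-minute to 4-hour sampling.  Using per-fix coordinates rather than a fixed
city centroid changes the elevation by well under a degree at city scale but
is the more defensible convention.  A "tracking day" is a distinct UTC
calendar date with at least one retained fix; UTC keeps the day boundary
timezone-independent.  Individuals need ≥ 30 tracking days after clipping to
qualify.

## Dispersal onset

Onset is the earliest date on which *all* fixes lie strictly outside the
1000-m territory circle (a day with any inside fix cannot be an onset
candidate — the conservative reading), with *no* fix at ≤ 1000 m during the
following 7 days (a single returning fix vetoes — the strictest reading).
Days without fixes inside the return window count as non-returns, since
absence of evidence cannot veto onset; such gaps are logged.  Tracks are
then truncated to ages ≤ 730 days from hatching.

## Movement models and AKDE

Three stationary isotropic candidates are fitted per individual: IID, OU
(position autocorrelation time `tau_pos`), and OUF (an additional velocity
time `tau_vel < tau_pos`).  Both correlated kinds are Markovian in a small
state vector, so the exact Gaussian likelihood is evaluated by a Kalman
innovation filter with closed-form discretisation at the observed irregular
time steps — O(n) per evaluation, with the long-run mean and the variance
scale profiled analytically.  Only the timescales are optimised numerically
(1-D golden-section for OU; Nelder–Mead over `(log tau_p, logit tau_v/tau_p)`
with two starts for OUF).  The innovation filter is implemented twice: a
compiled version used in fitting and a plain-R twin kept as the reference
implementation the tests compare against.

This is deliberately plain maximum likelihood with AICc selection rather
than a perturbative hybrid REML scheme: pHREML is a small-sample bias
refinement whose effect is second-order at the fix counts handled here, and
exact ML keeps the likelihood machinery transparent and oracle-checkable.
Correctness is established by simulation recovery (median parameter errors
≤ 25% at n ≈ 1000–2000) rather than by equality with any external package.
AICc uses `k` = 3/4/5 parameters (IID/OU/OUF) and `n` = number of fixes.
For IID data the *reported* `sigma2` is the bias-corrected sample variance
(the natural summary), while the log-likelihood is always the maximised
one, so AICc comparisons across kinds are coherent and the OU likelihood
converges to the IID likelihood as `tau_pos → 0`.

Range residency is checked on the empirical semi-variance function (per-axis
convention, averaged over axes).  The final quartile of lags counts as flat
when the pair-weighted regression slope is statistically indistinguishable
from zero *or* the fitted change across the quartile is below 10% of its
mean semivariance — with many pairs, a t-test alone flags ecologically
negligible trends as "expansion", so the relative criterion is needed.

The utilisation distribution is a Gaussian kernel mixture with per-axis
bandwidth `H = sigma2_hat * n_area^(-1/3)`, where the effective sample size
is `n_area = min(n, T_total / tau_p_hat)` for correlated kinds and `n` for
IID.  Irregular sampling is debiased by temporal-Voronoi weights: each fix
carries half the time gap to each neighbour, with the missing term clamped
to zero at the track ends.  This convention makes the density *exactly*
invariant under fix duplication; its price is that the two end fixes carry
half an interior weight under regular sampling.  Reported isopleth areas are
divided by `1 + 1/n_area`, a first-order small-sample debias; note this does
*not* remove the O(n^(-1/3)) kernel-smoothing inflation, which is visible in
the closed-form IID checks (≈ +8% at n = 2000, inside the 10% acceptance
band).  The grid uses cells of `sqrt(H)/4` padded three standard deviations
beyond the data.  Isopleths are the smallest densest cell sets reaching the
target mass; their areas get chi-squared intervals with `2 * n_area` degrees
of freedom — the standard DOF construction for a variance-like quantity
estimated from `n_area` effective locations, adopted here as a pragmatic
default since no single convention dominates the field.

## Temporal foraging areas

Field workflows typically delineate foraging clusters per homogeneous
habitat patch by expert inspection; this package substitutes a
deterministic, parameterised stand-in for that manual step: DBSCAN at
`eps = 150 m`, `min_pts = 10` (both configurable), with
optional splitting of clusters by habitat polygon or raster membership.
TFAs are 95% minimum convex polygons: the `ceiling(0.05 n)` points farthest
from the centroid are removed (distance ties: earlier timestamp first — a
determinism rule), then the convex hull is taken.  A cluster qualifies with
≥ 30 fixes spanning ≥ 10 calendar days.  The occupancy span is read as the
*central* 95% interquantile range of fix timestamps (0.975 − 0.025
quantiles, linearly interpolated, in days); the alternative reading (0.95
quantile of time since first fix) is available behind the `convention`
switch.

## GLMMs and the bootstrap LRT

Two random-intercept models relate TFA properties to mean human population
density: Poisson with log link for the occupancy span (rounded to whole
days, since a Poisson response must be integer) with the predictor
untransformed, and Gaussian on log area vs. log density (natural logs).
The Gaussian model is fitted by exact profiled ML (the marginal covariance
is block compound-symmetric, so GLS and both variances are closed-form given
the variance ratio, leaving a 1-D optimisation).  The Poisson model uses a
Laplace approximation with the per-group random-effect modes found by a
Newton iteration vectorised over groups.  PQL-style quasi-likelihoods were
deliberately not used: the parametric-bootstrap LRT needs comparable true
likelihoods under null and alternative.  The bootstrap simulates from the
fitted null (new random intercepts each replicate), refits both models, and
reports `p = (1 + #{T* ≥ T_obs}) / (n_boot + 1)`; replicates that fail to
refit are dropped and more than 10% failures abort.  Prediction bands use
the fixed-effect ("population level") variance with the central-`level`
normal quantile; at the probable-error level 0.6745 the half-width is
`qnorm(0.83725) ≈ 0.983` standard errors.

## Predictor stack and collinearity

Rasters live on a north-west-anchored grid with half-open cells and are
resampled to 50 m — area-weighted block means for continuous layers,
area-weighted majority with lowest-code ties for categorical ones.  Focal
aggregation at the three analysis scales (local 50 m, nesting territory
200 m, home range 1000 m) averages cells whose *centres* fall inside the
circle; centre membership is exactly reproducible, which matters more here
than the marginal accuracy gain of partial-cell weighting.  The
collinearity screen greedily removes, from the pair with the largest
Pearson |r| > 0.7, the variable with the lower univariate cross-validated
AUC (the "superior model performance" metric was not specified; univariate
CV-AUC is the natural choice inside a presence/background workflow and is
switchable via precomputed scores).

## Maxent

Maxent is solved directly as a concave L1-penalised Gibbs likelihood over
the background, by cyclic coordinate-wise proximal Newton updates with step
damping; convergence is declared on an objective change below `tol = 1e-5`
(at most 2500 sweeps).  Continuous covariates are min-max normalised on the
training range; features are linear, quadratic, pairwise products, and
forward/reverse hinges at 20 interior knots (a desk-scale stand-in for
dense hinge bases); categorical layers enter as one-hot indicators.  The
per-feature penalty is `beta_j = multiplier * s_j / sqrt(m)` with `s_j` the
presence-sample standard deviation — a simplification of the classical
per-class tuned tables that preserves the multiplier's role as a single
smoothness dial.  Raw output normalises to 1 over the training background;
the logistic output uses the conventional entropy transform with tau = 0.5.
Model selection is 10-fold cross-validation, stratified over presences and
background with the same folds reused across the 3 feature sets × 5
multipliers; the winner has the highest mean test AUC, ties broken by TSS
and then by the larger (smoother) multiplier.  The binarisation threshold is
the arithmetic mean of the per-fold max-SSS thresholds ("the average
threshold" is read as the fold average; computing it on the full model is a
switch away).  Area accounting multiplies suitable-cell counts by the cell
area, reports per-habitat-class totals, masks non-transferable regions
(peripheral forest/pasture), and subtracts 1000-m circular buffers around
occupied nests to quantify unoccupied suitable habitat.

## Synthetic worlds

`simulate_track()` draws positions from the *exact* transition
distributions of the stationary OU/OUF process at irregular times (no
Euler error), centred on the nest until the scripted onset day and on a
displaced centre (default 6 km, random direction) afterwards.  Defaults
describe a plausible pre-dispersal juvenile: sd 300 m around the nest
(`sigma2 = 9e4 m²`), `tau_pos` = 6 h, sampling intervals drawn from
{5, 15, 30, 60, 120, 240} minutes within a 06:00–18:00 UTC window, a 60-day
winter gap for long scenarios, and ~5% of fixes violating the HDOP/satellite
rule.  `simulate_landscape()` builds Gaussian-random-field layers (tree
cover and imperviousness clamped to [0, 100]%, population density ≥ 0), a
6-class habitat mosaic from jittered nearest-seed growth, and water as the
lowest ~5% of an independent smooth field.  Breeding sites are drawn without
replacement with probability ∝ exp(coefficients · covariates); the recovery
tests use a strong, a-priori-chosen signal (0.08 per % tree cover, +1.5 for
city parks) — the regime the acceptance criteria presuppose.  GLMM tables
draw population densities log-uniform on [1, 300] inhabitants/ha with
defaults anchored to the observed scales (intercept ≈ log 270 days; slope
−0.02 per inhabitant/ha).

What a green test establishes — and what it does not: the generators share
the analysis models' *form* (they are their exact inverses), so recovery
tests validate estimator correctness, not robustness to model
misspecification.  Real tracking data add location error, behavioural
non-stationarity and habitat-driven movement that the generators omit.

## Numerical choices and scaled-down test sizes

Monte-Carlo acceptance checks are scaled for a single CPU: the bootstrap
type-I calibration runs 200 repetitions × 99 bootstrap replicates (the
Monte-Carlo test is exact at α = 0.05 since (1 + 4)/(99 + 1) = 0.05), and
the Maxent recovery medians use 5 seeds.  Tolerances are never widened.
Isopleth closed-form checks take the median over 5 replicates because a
single 2000-point KDE's 50%-area fluctuates by ±5%.  Degenerate inputs are
handled explicitly: empty QC output is allowed, collinear MCP remainders
raise a degenerate-polygon error, constant predictor columns are dropped
with a warning, singular random-effect fits return `sigma2_u = 0` flagged,
and zero-variance Maxent covariates are dropped with a message.

## Known limitations

Anisotropic and non-stationary movement models, location-error filtering,
home-range overlap statistics, behavioural-state segmentation, MESS-style
extrapolation diagnostics and replicate-bootstrap Maxent are out of scope.
Raster I/O uses plain-text ESRI ASCII grids rather than GeoTIFF (no binary
codec dependency); GeoJSON is used for vector data.
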