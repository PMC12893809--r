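# urbanraptor

Movement-ecology and species-distribution tooling for urban raptor studies,
built around two questions: *where do dispersing juveniles concentrate their
foraging in a city*, and *how much of the city is environmentally suitable
for breeding*?

The package implements, as tested and reusable R code:

* **GPS tracking QC** — HDOP / satellite-count filters, a geometric solar
  elevation filter (daytime incl. nautical twilight, sun above −12°),
  study-region clipping, and a minimum-tracking-days qualification rule.
* **Natal-dispersal onset** by the distance-threshold rule: the first day on
  which all fixes lie outside a 1000-m circular parental territory
  (≈ 3.1 km²), with no return during the following 7 days; tracks truncated
  at age ≤ 730 days.
* **Continuous-time movement models** (IID, Ornstein–Uhlenbeck, OUF) fitted
  by exact maximum likelihood through a Kalman innovation filter, AICc
  selection, variogram range-residency checks, and **weighted,
  area-corrected autocorrelated kernel density estimates** (AKDE) whose 50%
  isopleths delineate core foraging ranges (CFRs).
* **Temporal foraging areas (TFAs)** — DBSCAN clusters of fixes inside the
  CFR, 95% minimum convex polygons, qualification (≥ 30 fixes over ≥ 10
  days), central-95% occupancy spans, and raster covariate extraction.
* **Random-intercept GLMMs** (Poisson on occupancy days; Gaussian on
  log-area vs. log human population density) with **parametric-bootstrap
  likelihood-ratio tests**.
* **A from-scratch Maxent** (L1-penalised Gibbs model over background cells)
  with linear/quadratic/product/hinge features, regularisation multipliers
  1–5, 10-fold cross-validation, max-SSS thresholding, binary maps and
  suitable-area accounting with 1000-m occupied-territory exclusion.
* **Synthetic data generators** (exact OU/OUF tracks with irregular diurnal
  sampling and winter gaps, Gaussian-random-field landscapes with a 6-class
  habitat mosaic, breeding sites from a known suitability surface, GLMM
  tables) so that every stage is testable against known ground truth.

The model core in brief: positions follow a stationary isotropic process
with autocovariance `σ² exp(−Δ/τ_p)` (OU) or
`σ² (τ_p e^{−Δ/τ_p} − τ_v e^{−Δ/τ_v})/(τ_p − τ_v)` (OUF); the utilisation
distribution is a Gaussian-kernel mixture with bandwidth
`H = σ̂² n_area^{−1/3}`, `n_area = min(n, T/τ̂_p)`; Maxent maximises
`mean_presence(λ·f) − log Σ_background e^{λ·f} − Σ_j β_j |λ_j|` with
`β_j = multiplier · s_j/√m`.

## Worked example

```r
library(urbanraptor)

# a synthetic juvenile: OU movement around the nest, emigration on day 40
tr  <- simulate_track(track_scenario(seed = 7, n_days = 200))
tr  <- daylight_filter(qc_filter(tr))
on  <- detect_onset(tr)
on
#> <dispersal_result> sim007: onset 2023-07-25 (radius 1000 m, window 7 d)
tr  <- dispersal_window(tr, on)

best <- select_model(list(fit_movement_model(tr, "IID"),
                          fit_movement_model(tr, "OU")))
best
#> <movement_model OU> sigma2 = 8.602e+04 m^2, tau_pos = 2.114e+04 s
#>   loglik = -18701.08, AICc = 37410.18 (n = 1480)

cfr <- range_contour(akde(tr, best), level = 0.5)
cfr
#> <range_contour 50%> area 0.414 km^2 (CI 0.383 - 0.447), 1 polygon(s)
```

The detected onset (2023-07-25) is exactly the scenario's day-40 emigration.
`sigma2` is the per-axis stationary variance of the movement process
(here ≈ (293 m)², close to the generating 300 m), `tau_pos` the position
autocorrelation time (≈ 5.9 h vs. the generating 6 h), and the 50% contour
is the core foraging range with its chi-squared confidence interval.
A full synthetic pipeline — QC → dispersal → CFR → TFA → GLMM and
predictors → Maxent → area report — runs from one call:

```r
run_pipeline(list(out_dir = "demo", seed = 1))
```

or from the installed CLI script
`system.file("cli", "urbanraptor.R", package = "urbanraptor")`.

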