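---
title: "Estimating overpass-time PM2.5 from fused satellite AOD with geographically weighted regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating overpass-time PM2.5 from fused satellite AOD with geographically weighted regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25gwr)
```

## The estimation problem

Ground monitoring networks measure PM2.5 accurately but sparsely;
satellite aerosol optical depth (AOD) covers whole regions but measures
column-integrated light extinction, not surface mass concentration, and
the relationship between the two varies in space. `pm25gwr` implements a
calibration pipeline that estimates ground-level PM2.5 at satellite
overpass time from AOD and same-moment meteorology, with a
location-varying linear model:

$$
\mathrm{PM}^{rev}_{l,d} = \beta_{0,l,d}
  + \beta_{1,l,d}\,\mathrm{AOD}^{rev}_{l,d}
  + \beta_{2,l,d}\,\mathrm{Prec}^{last}_{l,d}
  + \beta_{3,l,d}\,\mathrm{ST}_{l,d}
  + \beta_{4,l,d}\,\mathrm{PS}_{l,d}
  + \beta_{5,l,d}\,\mathrm{WS}_{l,d}
$$

with $l$ a location and $d$ a day. Both sides are *physically revised*
before fitting:

* **Vertical correction.** Aerosol is assumed well mixed within the
  planetary boundary layer, so `revise_aod()` divides column AOD by
  boundary-layer height (km), giving a near-surface extinction proxy in
  1/km. Division (not multiplication) is the standard boundary-layer
  normalisation: a shallow layer concentrates the same column burden
  near the surface.
* **Hygroscopic correction.** Stations report dry mass, while ambient
  particles swell with humidity; `revise_pm25()` inflates the dry
  measurement by $(1 - \mathrm{RH}/100)^{-1}$. The factor diverges at
  saturation, so rows wetter than `rh_cap` (default 95 %) are excluded
  rather than extrapolated, and predictions are reported back on the dry
  scale through the exact inverse `dry_pm25()`.

The response uses the *previous* local day's total precipitation
(`last_prec`), a wet-scavenging proxy; surface temperature (K), surface
pressure (Pa) and wind speed (m/s, the magnitude of the u/v components)
complete the regressors.

## Data preparation

**AOD fusion.** Dark Target (DT, 3 km) retrievals fail over bright
desert and urban surfaces; Deep Blue (DB, 10 km) covers them. After
quality filtering (DT kept only at QA = 3, DB at QA ≥ 2),
`regrid_db_to_fine()` assigns each fine cell the coarse cell containing
its center — containment rather than interpolation, so retrievals are
never smeared across surface-type boundaries — and `fuse_dt_db()` takes
DT wherever it is valid, else DB. The fused field never invents a value
and its missing set is exactly the intersection of the inputs' missing
sets.

**Collocation.** The polar orbiter observes at about 13:30 local solar
time, while station records are stamped on the Beijing clock (UTC+8)
across a domain spanning five nominal 15° time-zone bands
(`zone_offset()`). For each station-day the overpass value is the mean
of the local 13:00 and 14:00 records; if exactly one exists it is used
alone (a permissive reading of "averaged", logged per row). AOD is
taken from the *containing pixel* at the station, meteorology by
*bilinear interpolation* — deliberately different access rules,
matching how each product is defined. Cell membership is half-open
([west, east) × [south, north)): a point on a shared edge belongs to
the cell whose west or south edge it is. Rows missing any ingredient
are excluded and counted, never imputed.

## The GWR estimator

`fit_gwr()` calibrates the model at every station by weighted least
squares, weighting observation $i$ by a kernel of its great-circle
distance (haversine, R = 6371 km — the domain is too tall for degree
Euclidean distances) from the calibration point. The default kernel is
the **adaptive bisquare** $(1-(d/b)^2)^2$ for $d<b$, zero beyond: its
compact support suits a network that is dense in cities and sparse in
the west, because the bandwidth $b$ — the distance to the $k$-th
nearest station — shrinks and grows with local density. A Gaussian
kernel and a uniform kernel (the global-OLS limit, used as an oracle in
the tests) are available by configuration.

The neighbour count $k$ is chosen by minimising the leave-one-out
residual sum of squares of the local fits, searched golden-section over
integers with an exhaustive sweep once the bracket is narrower than 10;
ties break toward the smallest $k$ (locality). Because coefficients
carry both $l$ and $d$ subscripts, one GWR is fitted per day; to keep
the selection affordable and stable, one $k$ is selected per season as
the median of per-day selections on a spread of sampled days (default
5) and applied to every day of that season. The selection therefore
sees all rows of the sampled days — a deliberate, mild departure from
strict fold hygiene that affects only the integer $k$, not the
coefficients; the cross-validation refits every coefficient without the
held-out rows.

Numerical choices worth stating:

* Local fits solve the weighted QR; the independent test oracle solves
  the normal equations. The fit requires at least 7 positively weighted
  rows and errors on rank deficiency — with one documented exception: a
  regressor that is *constant* across the local support (typically an
  all-dry precipitation neighbourhood, the common case since most
  previous-day precipitation is zero) carries no local information and
  is dropped with slope 0, the constant being absorbed by the
  intercept. Duplicated or collinear varying columns remain a hard
  error naming the location.
* The minimum admissible $k$ is 8 (regressors + 2): under the bisquare
  kernel the $k$-th neighbour itself gets weight exactly zero, so
  smaller $k$ would leave the local fit under-determined.
* Local $R^2$ is the weighted $1 - \sum w e^2 / \sum w (y-\bar y_w)^2$.
* Singular fits at prediction points yield missing values by default
  rather than falling back to the global fit.
* Predictions carry an extrapolation guard: if the target's
  design-space leverage $x'(X'WX)^{-1}x$ exceeds `max_leverage`
  (default 1), the local prediction would be less precise than a single
  raw observation and is returned as missing and counted. The
  archetypal trigger is a wet station inside an otherwise dry kernel:
  the local precipitation slope is then estimated from near-zero
  variation and extrapolated far outside its support, which can produce
  arbitrarily wild values. Typically 2-3 % of held-out rows on the
  default noisy scene are flagged, concentrated where the network is
  sparse — the same instability the field reports for sparsely
  monitored regions.

`predict_gwr()` calibrates a local model *at* each target point from
the day's station rows and evaluates it with the point's own
regressors, on the revised scale; `crossval()` back-transforms with the
point's RH before comparing against measured (dry) PM2.5 — validation
happens on the scale stations actually report.

## Validation

`crossval()` partitions rows into 10 random folds *within each season*
(record-level folding; spatial leave-station-out CV is a noted
extension, not implemented). Each fold is predicted from per-day fits
on the other nine; every row is validated exactly once, and a test
corrupts a held-out response to verify its own prediction cannot see
it. Metrics follow the scatter-plot convention: $R^2$ is the squared
Pearson correlation of estimated against measured, with the
sum-of-squares definition reported as a secondary column; the slope and
intercept come from the OLS line estimated = a·measured + b. Because
held-out predictions are locally smoothed, measurement noise attenuates
this line: slope below 1 and positive intercept — overestimation of low
and underestimation of high concentrations — is the expected signature,
and the suite asserts it.

Seasons are meteorological (MAM/JJA/SON/DJF). Seasonal surfaces from
`seasonal_mean()` mask cells with fewer than 5 valid days, and
`who_exceedance_pct()` reports relative excess over the WHO interim
targets (IT-1 = 35, IT-3 = 15 µg/m³).

## The synthetic scene generator

Real granule, reanalysis and station feeds are not bundled; the
generator closes the loop so that every stage is testable and the whole
pipeline can be validated against a known truth. It emulates, on a
10° × 10° window straddling a time-zone band edge:

* **Coefficient surfaces** — each $\beta_j$ is its mean plus a
  superposition of 4 random plane sinusoids (wavelengths at or above a
  10° correlation length, absolute weights summing to 1). Sinusoids
  rather than Gaussian-process draws: exact reproducibility, point
  evaluation anywhere, and a closed-form bound on cell-to-neighbour
  roughness that the suite checks against the realised wave tables.
* **Station network** — 400 stations, a fraction `clustering` (0.5)
  drawn around 6 urban centers, the rest uniform; occupancy statistics
  are tested against the uniform baseline.
* **Meteorology** — each field is a smooth standard-normal field (12
  superposed waves, 3° synoptic correlation length) pushed through the
  quantile function of its marginal family: log-normal PBLH (~0.9 km)
  and surface temperature (~288 K), Weibull RH (mean 55 %, capped at
  95 %), normal pressure (~960 hPa) with an optional two-mode mixture
  emulating a high plateau, normal wind components, zero-inflated
  exponential precipitation (80 % dry).
* **Latent extinction** — the revised-AOD truth is log-normal
  (median 0.45/km) with its own 0.7° correlation length: aerosol
  plumes decorrelate over ~100 km, much faster than synoptic fields,
  and it is precisely this short-scale contrast within a kernel that
  identifies the local AOD slope.
* **Granules** — column AOD = latent extinction × PBLH on the fine
  grid; DT carries it with retrieval noise and iid bright-surface
  missingness (15 %), DB is its block average on the coarse grid with
  noise; QA flags are drawn from configured distributions.
* **Observations** — the revised PM2.5 at a station is the regression
  identity evaluated with the *same collocation rules the pipeline
  uses* (pixel AOD over bilinear PBLH, bilinear meteorology), plus
  Gaussian noise (sd 10 µg/m³ on the revised scale); the recorded dry
  value is deflated by $(1-\mathrm{RH}/100)$ and written as two hourly
  records around local 13:00/14:00 with small jitter (sd 1.5 µg/m³).

The `noiseless = TRUE` preset zeroes every noise source, the bright
mask and sub-top QA draws; on such a scene the pipeline must reproduce
the recorded PM2.5 essentially exactly (the closure check), proving the
generator and estimator share one model. With spatially constant
coefficients the reproduction is exact to machine precision; with the
default smooth surfaces a small local-stationarity bias remains (the
kernel sees a window of a curved surface), which is why closure is
asserted at R² ≥ 0.99 and RMSE ≤ 0.5 µg/m³ rather than at 1e-8.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: cloud contamination and retrieval biases
correlated with surface type, instrument changeovers, political (rather
than solar) time zones, terrain-driven meteorology gradients sharper
than the configured correlation lengths, and any AOD–PM relationship
outside the linear revised-scale model. Results on the scene
demonstrate the estimator's correctness and its statistical behaviour
under the stated conditions, not the real-world accuracy of
satellite-derived PM2.5.

## Problem sizes and runtime choices

The default scene (400 stations × 30 days, 0.03° fine grid) yields
about 11 500 complete rows after exclusions; a full 10-fold seasonal CV
plus daily fits runs in well under a minute, and the closure scene uses
3 days. Bandwidth selection dominates cost — LOO CV is $O(n^2)$ per
candidate — which motivates both the golden-section search and the
per-season median-$k$ rule.

## Worked example

```{r example, eval = FALSE}
sc <- scene_config()          # the default study scene
scene <- simulate_scene(sc, seed = 1)
rows <- scene_model_rows(scene)
cfg <- run_config(domain = sc$domain)

cv <- crossval(rows, cfg, seed = 8)
cv
#> <cv_report> 1-season cross-validation (0 rows skipped)
#>  season     n     r2  r2_ss  rmse   mae  slope intercept
#>  winter 11233 0.9016 0.9015 5.528 4.159 0.9124     3.253

who_exceedance_pct(60, who_it_levels[["it3"]])
#> [1] 300
```

## Known limitations

* Real MODIS HDF, GRIB reanalysis and station-feed decoding are out of
  scope; the reader seam is the documented CSV dialects.
* Record-level folding can place a station's other days in the
  training set; spatially blocked CV would be stricter.
* Per-day fits ignore temporal coherence of the coefficient surfaces.
* The DT-over-DB precedence is the simplest complementary-advantage
  rule; no weighted blending of overlapping retrievals is attempted.
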