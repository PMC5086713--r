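# pm25gwr

Ground-level PM2.5 estimation from satellite aerosol optical depth
(AOD) at overpass time, for air-quality and exposure-assessment work
where monitoring stations are too sparse to map concentrations alone.

Satellite AOD measures light extinction over the whole atmospheric
column; stations measure dry particle mass at the surface; and the
relationship between the two drifts across a continental domain. The
package implements the full calibration chain:

1. **AOD fusion** — Dark Target (3 km) retrievals, which fail over
   bright desert/urban surfaces, are quality-filtered (QA = 3) and
   gap-filled with quality-filtered Deep Blue (10 km, QA ≥ 2) values
   brought onto the fine grid by containment regridding.
2. **Physical corrections** — column AOD is divided by planetary
   boundary layer height (`revised_aod = AOD / PBLH`, a near-surface
   extinction proxy), and dry station PM2.5 is inflated by the
   hygroscopic growth factor (`revised_pm25 = PM2.5 (1 − RH/100)⁻¹`).
3. **Collocation** — station records, stamped in Beijing time across
   five solar time-zone bands, are averaged at local 13:00/14:00
   (satellite overpass); AOD is read from the containing pixel,
   meteorology bilinearly interpolated; complete cases only.
4. **Geographically weighted regression** — per day *d* and location
   *l*:

   ```
   Revised_PM2.5(l,d) = β0(l,d) + β1(l,d)·Revised_AOD + β2(l,d)·Last_Prec
                        + β3(l,d)·ST + β4(l,d)·PS + β5(l,d)·WS
   ```

   fitted by locally weighted least squares under an adaptive bisquare
   kernel whose bandwidth is the great-circle distance to the k-th
   nearest station, k chosen by leave-one-out cross-validation.
5. **Validation and reporting** — seasonal 10-fold cross-validation
   (R², RMSE, MAE, regression slope/intercept of estimated on
   measured, all on the dry scale), seasonal mean surfaces, and
   exceedance of the WHO interim targets (35 and 15 µg/m³).

Because the real granule/reanalysis/station feeds are not distributable,
the package ships a deterministic **synthetic scene generator**
(`simulate_scene()`) that emulates the study conditions — clustered
station networks, smooth spatially varying coefficient surfaces,
log-normal/Weibull meteorology, paired DT/DB granules with QA flags and
bright-surface gaps — so the entire pipeline is testable end to end
against a known truth.

## Worked example

```r
library(pm25gwr)

sc    <- scene_config()                 # 400 stations, 30 winter days,
scene <- simulate_scene(sc, seed = 1)   # noise sd 10 ug/m3 (revised)
rows  <- scene_model_rows(scene)        # fuse + collocate + correct
cfg   <- run_config(domain = sc$domain)

crossval(rows, cfg, seed = 8)
#> <cv_report> 1-season cross-validation (0 rows skipped)
#>  season     n     r2  r2_ss  rmse   mae  slope intercept
#>  winter 11233 0.9016 0.9015 5.528 4.159 0.9124     3.253

who_exceedance_pct(60, who_it_levels[["it3"]])
#> [1] 300
```

Reading the output: of 12 000 station-days, 11 513 survive complete-case
collocation (487 lose their AOD pixel or exceed the RH cap), and 280
held-out predictions are flagged as local extrapolations and excluded.
The remaining estimates explain 90 % of the variance in measured PM2.5
with a typical error of 4–6 µg/m³. The regression line of estimated on measured has
slope 0.92 and intercept 3.1 µg/m³ — the attenuation signature of a
locally smoothed estimator: low concentrations are slightly
overestimated, high ones underestimated. A 60 µg/m³ winter mean exceeds
the WHO IT-3 level (15 µg/m³) by 300 %.

A thin command-line wrapper over the same functions is installed at
`inst/cli/pm25gwr.R` (subcommands `simulate`, `rows`, `fit`, `cv`).

## Package layout

| Area | Files |
|---|---|
| Grids, stations, configuration | `R/grid.R`, `R/stations.R`, `R/config.R` |
| Physical corrections | `R/corrections.R` |
| DT/DB fusion | `R/fusion.R` |
| Collocation & model rows | `R/integration.R` |
| GWR core | `R/gwr.R` |
| Cross-validation & metrics | `R/evaluation.R` |
| Seasonal surfaces, WHO exceedance | `R/reporting.R` |
| Synthetic scenes | `R/scene.R`, `R/pipeline.R` |

The methods vignette (`vignettes/methods.Rmd`) documents the model,
its assumptions, every tunable parameter, and what the synthetic
scenes do and do not demonstrate about real data.
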