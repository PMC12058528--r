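# ulexp

Unprecedented lifetime exposure to climate extremes across birth cohorts.

## What it does, and for whom

As the climate warms, the extremes a person accumulates over a lifetime —
heatwaves, crop failures, droughts, river floods, wildfires, tropical
cyclones — can exceed anything a pre-industrial climate would plausibly
have delivered. `ulexp` is for climate-impact and population researchers
who want to quantify that: it projects, per birth cohort and warming
pathway, the fraction of people whose *cumulative lifetime exposure*
crosses a rigorously calibrated pre-industrial threshold.

The core quantities, in the field's notation:

* **Lifetime exposure.** With `f(x, t) ∈ [0, 1]` the annual exposed area
  fraction of 0.5° grid cell `x` and `L` the birth cohort's life
  expectancy,

  ```
  E(x, b) = Σ_{k=0}^{⌊L⌋−1} f(x, b + k)  +  (L − ⌊L⌋) · f(x, b + ⌊L⌋)
  ```

  — full years in full, the death year by the fraction lived.

* **ULE threshold.** `T(x)` is the nearest-rank 99.99th percentile of a
  pooled sample of bootstrapped pre-industrial lifetime exposures (10,000
  per control run; four runs give the canonical 40,000 per cell). A cohort
  at `x` reaches **unprecedented lifetime exposure** when `E(x, b) > T(x)`
  strictly — an outcome with at most a one-in-ten-thousand chance absent
  climate change.

* **Cohort fraction.** `CF(b, p)`: emerged people (whole cells count
  all-or-nothing) divided by the cohort total, per birth year `b`
  (1960–2020) and GMT pathway `p` (1.5–3.5 °C by 2100 in 0.1 °C steps — 21
  pathways), summarised across the model ensemble valid for that pathway.

Exposure ensembles are re-expressed along the pathways by warming-level
matching: each run's GMT series is smoothed with a 21-year rolling mean and
every pathway year borrows the run year of closest smoothed warming,
provided the worst discrepancy stays within 0.2 °C. Emergence can further
be stratified by population-weighted quintiles of a deprivation index or of
lifetime-mean GDP per capita.

Because the real input archives are large, the package includes a
first-class synthetic-data generator (`synth_config()`,
`gen_exposure_ensemble()`, `gen_demographics()`, `gen_vulnerability()`,
`gen_gmt_anchors()`) with exact analytic ground truth
(`true_cohort_fraction()`, `true_ule_quantile()`), so the entire pipeline
is testable offline with known answers.

## Worked example

A synthetic world on a 10×10 grid, 4 countries, 4 model runs spanning
RCP2.6–8.5, evaluated for three birth cohorts along the 1.5/2.5/3.5 °C
pathways:

```r
library(ulexp)

cfg <- ule_config(
  synthetic = list(n_lat = 10, n_lon = 10, n_countries = 4, seed = 11),
  birth_years = c(1960, 1990, 2020),
  pathway_lo = 1.5, pathway_hi = 3.5, pathway_step = 1.0,
  n_boot = 10000, seed = 11)

res <- run_ule_pipeline(cfg)
#> [pathways] ensemble sizes: 1.5:4 2.5:3 3.5:2
#> [baseline] bootstrapping 4 x 10000 pre-industrial lifetimes
#> ...
print(res)
#> <ule_result> 3 birth years x 3 pathways (2-4 runs per pathway)
#>   headline (ensemble-mean CF, last birth year):
#>     pathway 1.5: CF = 42.2%
#>     pathway 2.5: CF = 63.2%
#>     pathway 3.5: CF = 87.4%

dplyr::filter(res$cf_summary, birth_year == 2020)
#>   pathway birth_year cf_mean cf_median cf_q25 cf_q75 cf_min cf_max n_runs
#> 1     1.5       2020   0.422     0.424  0.383  0.463  0.366  0.476      4
#> 2     2.5       2020   0.632     0.624  0.611  0.648  0.598  0.672      3
#> 3     3.5       2020   0.874     0.874  0.873  0.874  0.872  0.875      2
```

Reading this: only runs warm enough to serve a pathway within the 0.2 °C
matching constraint enter its ensemble, so membership shrinks from 4 runs
at 1.5 °C to 2 at 3.5 °C. For people born in 2020 in this world, the
ensemble-mean cohort fraction reaching unprecedented lifetime exposure
rises from 42% under a 1.5 °C pathway to 87% under 3.5 °C, while the 1960
cohort stays below 10% everywhere — warming, not demography, drives the
divergence. Per-cell emergence thresholds sit at 4–8 events
(`res$thresholds`; median 6 here), and `summary` objects plot directly:
`autoplot(res$cf_summary)`, `plot_cf_heatgrid(res$cf_summary)`,
`plot_baseline_distribution(res$baseline, cell = 1)`. Broom-style
`tidy()`/`glance()` methods expose results as tibbles.

The calibration guarantee behind the threshold can be checked directly:

```r
cal <- ule_calibration(n_cells = 10, seed = 11)
mean(cal$non_exceedance)
#> [1] 0.99997
```

i.e. fresh same-distribution lifetimes land at or below the bootstrap
threshold 99.997% of the time — the one-in-ten-thousand rule holds.

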