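---
title: "Methods: unprecedented lifetime exposure to climate extremes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unprecedented lifetime exposure to climate extremes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimand

A person born in year $b$ in grid cell $x$ accumulates exposure to a class
of climate extreme (heatwaves, crop failures, droughts, river floods,
wildfires, tropical cyclones) over their lifetime. With $f(x,t) \in [0,1]$
the annual exposed area fraction of the cell and $L$ the life expectancy of
the birth cohort (country-level, applied uniformly within the country),
lifetime exposure is

$$E(x,b) \;=\; \sum_{k=0}^{\lfloor L\rfloor - 1} f(x,\,b+k)\;+\;
(L-\lfloor L\rfloor)\, f(x,\,b+\lfloor L\rfloor),$$

i.e. every fully lived year counts in full and the death year counts by the
fraction of it lived. All people in a cell are considered exposed when the
extreme occurs in the cell — exposure is all-or-nothing at the 0.5° scale.

Exposure is called *unprecedented* (ULE) when $E(x,b)$ strictly exceeds the
99.99th percentile of lifetime exposures expected in a stationary
pre-industrial climate at that cell — an outcome a person had at most a
one-in-ten-thousand chance of experiencing without climate change. The
package's headline estimand is the **cohort fraction** CF$(b,p)$: the share
of the global (or country) birth cohort $b$ living in cells that reach ULE
under a warming pathway $p$, summarised across an ensemble of climate ×
impact model projections by its mean (headline), median, quartiles and
range.

## The pre-industrial null and the emergence threshold

For each pre-industrial control projection (a stationary simulation of
239–639 years), `bootstrap_preindustrial()` draws $\lceil L\rceil$ years
iid with replacement and sums them with the fractional-final-year rule,
10,000 times per run, using the 1960 cohort's life expectancy. Samples are
pooled across control runs — four runs give the canonical 40,000 lifetime
exposures per cell. Resampled year indices are shared across the cells of a
country, so each replicate is a country-wide *map* of lifetime exposure;
per-cell marginals are unaffected, and the draws for distinct (run,
country) pairs come from independent seed streams derived from the master
seed, making results independent of execution order.

`ule_threshold()` takes the nearest-rank percentile — the sorted sample's
element at rank $\lceil (p/100)\,n\rceil$ — so the threshold is always an
achievable sample value. Emergence (`detect_emergence()`) uses *strict*
exceedance, $E > T$: with integer-valued event counts this is the
conservative reading of "passing" the threshold, and it makes the
calibration guarantee exact (the probability of a same-distribution
lifetime strictly exceeding the empirical 99.99th percentile is at most
about $10^{-4}$). `ule_calibration()` measures exactly this: stationary
cells, a bootstrap threshold, fresh same-distribution lifetimes — the mean
non-exceedance across cells should be at least 99.99%.

Why 99.99 and not further out? A pooled sample of 40,000 resolves the
99.99th percentile with a handful of expected exceedances; the 99.999th
nearest-rank percentile of the same pool is its maximum. For rare hazards
(expected lifetime counts well below one) the two differ by at most one
event in ≥95% of cells — the sensitivity has levelled off. For frequent
hazards the sample maximum is materially noisier, which is precisely why
the 99.99th percentile is the limit of reliable information in a pool of
this size. `bootstrap_preindustrial()` warns when the pooled size leaves
fewer than four expected points beyond the requested percentile.

## Warming pathways and year resampling

Projections exist only for a few emissions scenarios, so exposure series
are re-expressed along 21 prescribed GMT pathways (1.5–3.5 °C by 2100 in
0.1 °C steps, `build_pathways()`), each interpolated year-wise between the
two anchor trajectories bracketing it by their 2100 levels. Each run's GMT
series is smoothed with a centred 21-year rolling mean (`smooth_gmt()`);
`map_years()` then matches every pathway year to the run year of closest
smoothed warming. A mapping is valid only if the largest warming
discrepancy over 1960–2113 is at most 0.2 °C; otherwise it is flagged and
`resample_exposure()` refuses it. Because cooler runs cannot serve hotter
pathways, ensemble size is non-increasing in pathway level
(`ensemble_sizes()` reports membership; the pipeline logs empty ensembles
explicitly).

Three conventions the matching needs but that are genuinely open were fixed
as follows and are recorded in every run manifest:

* **Edge rule.** The rolling mean shrinks its window symmetrically at the
  series edges (at position $i$ the half-window is
  $\min(10, i-1, n-i)$), so 1960s years are retained rather than discarded.
  Constant and linear series pass through unchanged everywhere, which makes
  the rule testable.
* **Tie rule.** Ties in the closest-warming search go to the earliest
  source year (deterministic, and biased toward less-warmed analogue years,
  limiting overshoot in low pathways). Near-ties within $10^{-9}$ °C are
  treated as ties so the rule is invariant to floating-point asymmetry.
* **Interpolation.** Pathways use only the two bracketing anchors — no
  global fit — and an anchor at exactly a target level passes through
  unchanged.

One methodological caveat the ground-truth machinery makes precise: where a
pathway plateaus, the matching reuses the same source year for several
target years. Reuse preserves the mean of lifetime exposure but inflates
its tail relative to the iid bootstrap null (a year drawn with multiplicity
$m$ contributes $m$ events at once). The package's analytic oracle
accounts for multiplicities exactly; users comparing mapped lifetimes
against the iid null should be aware the comparison is slightly
anti-conservative on plateaus.

## Demographics

Demographic inputs arrive as 5-year tables and are annualized exactly as
the analysis needs them:

* Life expectancy of 5-year-olds per 5-year block (1950–1955 … 2015–2020)
  is interpolated linearly between block midpoints, held constant outside
  the outermost midpoints (interpolation is specified; constant extension
  is the conservative completion), and increased by 5 years to convert to
  life expectancy since birth. The maximum 2020-cohort life expectancy
  fixes the final analysis year, 2113.
* Gridded population (through 2100) is extended to 2113 by a recursive
  10-year trailing mean: 2101 is the mean of 2091–2100, and filled years
  enter subsequent means.
* 5-year × 5-year cohort tables (1950–2100, age groups 0–4 … 95–99, 100+)
  are split as total/5 into single-year ages (100+ maps to single age 100
  undivided), interpolated linearly across table years, and extrapolated
  linearly to 2113 from the last two annual values with negatives clamped
  to zero (and a warning). Re-aggregating annualized ages at table years
  reproduces the source totals to within $10^{-6}$ relative — the
  conservation property the tests assert.
* Birth-cohort size at a cell is the cell's population in the birth year
  times the country's relative age-0 share for that year — spatially
  homogeneous cohort structure by assumption.

A cohort born in year $b$ with life expectancy $L$ lives calendar years
$b,\dots,b+\lfloor L\rfloor-1$ in full and fraction $L-\lfloor L\rfloor$ of
year $b+\lfloor L\rfloor$ (birth at the start of the year); lifetimes
extending past the data are truncated with a warning rather than guessed.

## Vulnerability strata

Two grid-scale indicators are supported: a deprivation index on a 0–100
scale (higher = more deprived; a single map treated as representative of
2020) and lifetime-mean GDP per capita, computed per birth cohort from an
annual GDP series (copy-forward extended to 2113) divided by population and
averaged over the lifetime with the final-year fraction. For each birth
year, cells are ranked by the indicator and cut into five bins of nearly
equal cohort population: walking the ranked cells, a bin closes at the
first cell whose cumulative population reaches $i/5$ of the total, with
that boundary cell kept in the lower bin. Cells are never split, so bins
are only approximately equal — with very uneven cell populations a bin can
even end up empty, which is the price of the deterministic no-splitting
rule. Binning depends on the indicator only through ranks, hence is
invariant under strictly monotone transforms; ties break by cell index.

The bottom and top 20% are compared by their emerged fraction per ensemble
member. The significance test is a two-sided Welch $t$ across members at
$\alpha = 0.05$; when either group has zero variance (common with
saturated emergence) an exact rank-sum test with midranks, computed by full
enumeration of group assignments, takes over; two identical constant groups
are reported as not significant with a flag. The choice of test is a
documented convention, not a reconstruction, and travels in the output.

## The synthetic world and its ground truth

Real inputs (gridded impact-model exposure archives, national demographic
tables, deprivation maps) are large; the package therefore ships a
generator whose outputs are structurally identical to them and whose truth
is known:

* **Occurrence model.** Annual Bernoulli per cell with probability
  $p(x,t) = \mathrm{clamp}(p_0(x) + \beta(x)\,W_s(t),\,0,\,1)$, where
  $W_s$ is the run's smoothed GMT anomaly; exposed fraction given
  occurrence is a per-cell constant $a(x)$. This is the simplest model in
  which event frequency increases with warming while lifetime exposure
  keeps a closed-form (scaled Poisson-binomial) distribution.
* **Defaults.** $p_0 = 0.01$ (a once-per-century event, the order of the
  study's extreme-heat definition), $a = 1$ (whole-cell hazards),
  $\beta = 0.05\,^\circ\mathrm{C}^{-1}$ — chosen so the default world
  reproduces the qualitative regime of interest: early cohorts rarely
  emerge, the 2020 cohort's CF rises steeply with pathway level, and the
  emergence threshold sits at ~5–6 events. Controls are 239–639 years
  (default 439); four runs (one impact model × four GCM labels across
  RCP2.6/6.0/8.5) give the canonical ensemble; scenario end-of-century
  warming is 1.6/2.7/4.4 °C with AR(1) interannual noise of 0.05 °C.
* **GMT anchors** share a historical backbone (0.3 °C in 1960, 1.2 °C in
  2020) and fan out linearly to hit their nominal level exactly in 2100,
  constant thereafter — monotone in time and pointwise monotone in level,
  so low pathways never overshoot.
* **Demography and vulnerability.** Life expectancy blocks rise linearly
  (60 → 73 years across 1950–2015, ±1.5 years between countries; +5 after
  interpolation keeps 2020 lifetimes within 2113); cohort age structure is
  a geometric decay over age groups; gridded population uses fixed
  lognormal cell weights times a 1%/yr growth curve. The deprivation index
  is coupled to baseline GDP per capita through a Gaussian copula at a
  configurable Spearman correlation (default −0.7; −1 forces exact reverse
  ranking).

What the generator does **not** emulate — spatial autocorrelation of
extremes, multi-hazard dependence, climate-model bias structure, migration
and demographic feedbacks — bounds what passing tests show: they verify the
pipeline's statistics and bookkeeping, not the realism of any particular
hazard archive.

The ground-truth layer computes, exactly, the probability that a synthetic
lifetime exceeds a threshold: the mapped lifetime is
$a\sum_s w_s X_s$ over distinct source years with integer multiplicities
$w_s$ (plus one fractionally weighted final source handled by
conditioning), so tail probabilities come from lattice convolution, with no
Monte-Carlo error. `true_cohort_fraction()` conditions on the realized
thresholds and year mappings — both fixed by the seed and independent of
the future occurrence draws — so the only randomness separating measured
from true CF is Bernoulli sampling, whose exact variance it also returns.
Measured ensemble-mean CF is required to sit within 3 such SDs of truth;
`stationary_false_emergence()` and `true_ule_quantile()` provide the
$\beta = 0$ closed forms.

## Numerical conventions and degenerate inputs

* Nearest-rank percentiles throughout (thresholds are sample elements);
  quantile interpolation is never used for emergence.
* Occurrence from raw indicators (`occurrence_from_indicator()`) uses
  strictly-above comparison against the cell's control percentile and
  refuses controls shorter than $1/(1-q/100)$ years.
* Zero cohort totals yield flagged-NA cohort fractions excluded from
  ensemble statistics; populated cells without a country assignment,
  countries missing from demographic tables, and exposure fractions
  outside $[0,1]$ are hard errors naming the offending cell/table.
* All randomness flows from one master seed through `derive_seed()`
  (a deterministic string hash), so every stage is reproducible
  independently of execution order; reruns are bit-identical.

## Problem sizes used by the test suite

The suite exercises the statistical guarantees at deliberately moderate
sizes chosen as the smallest that leave the Monte-Carlo bands meaningful:
threshold calibration at 100 independent cells (639-year controls, 40,000
bootstrap + 10,000 validation lifetimes each); parameter recovery on a
20×20-cell, 4-run, 3-pathway world with 10,000 bootstrap replicates per
run; null calibration of the strata test over 100–200 repetitions; and
smaller worlds for structural checks. Headline numbers from the study this
design mirrors (e.g. country-level cohort fractions from the full
impact-model archive) require the original data archives and are out of
scope for the synthetic tests.
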