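test_that("bootstrap pools runs x replicates and reproduces resampling means", {
  # 4 control runs x 10,000 replicates -> pooled sample of 40,000
  ctrl <- tidyr::expand_grid(run = paste0("r", 1:4), year = 1:250, cell = 1) |>
    dplyr::mutate(f = 0)
  bs <- bootstrap_preindustrial(ctrl, 60, n_boot = 10000, seed = 1)
  expect_equal(ncol(bs$samples), 40000)
  # all-zero control gives all-zero lifetime exposures
  expect_true(all(bs$samples == 0))

  # resampling-mean identity: pooled mean within 3 SE of L * realized rate
  set.seed(41)
  ctrl2 <- tibble::tibble(run = "r1", year = 1:639, cell = 1,
                          f = as.numeric(runif(639) < 0.01))
  p_hat <- mean(ctrl2$f)
  bs2 <- suppressWarnings(
    bootstrap_preindustrial(ctrl2, 60, n_boot = 10000, seed = 2))
  se <- sd(bs2$samples[1, ]) / sqrt(10000)
  expect_lt(abs(mean(bs2$samples[1, ]) - 60 * p_hat), 3 * se)

  # determinism under a fixed seed
  bs3 <- suppressWarnings(
    bootstrap_preindustrial(ctrl2, 60, n_boot = 1000, seed = 7))
  bs4 <- suppressWarnings(
    bootstrap_preindustrial(ctrl2, 60, n_boot = 1000, seed = 7))
  expect_identical(bs3$samples, bs4$samples)

  # under-sized pooled samples trigger the reliability warning
  expect_warning(
    bootstrap_preindustrial(ctrl2, 60, n_boot = 1000, seed = 1),
    "unreliable")
})

test_that("the ULE threshold is the nearest-rank percentile of the pool", {
  ctrl0 <- tibble::tibble(run = "r1", year = 1:250, cell = 1, f = 0)
  bs0 <- suppressWarnings(bootstrap_preindustrial(ctrl0, 60, n_boot = 1000))
  expect_equal(ule_threshold(bs0)$threshold, 0)

  # binomial quantile oracle: lifetime sums from a Bernoulli(0.01) control
  # are Binomial(60, m/639); with the realized control rate close to 0.01
  # the analytic CDF puts the 99.99th percentile at 5:
  # P(X <= 4) = 0.99965 < 0.9999 <= P(X <= 5) = 0.99997
  expect_lt(pbinom(4, 60, 0.01), 0.9999)
  expect_gte(pbinom(5, 60, 0.01), 0.9999)
  set.seed(57)
  ctrl <- tibble::tibble(run = "r1", year = 1:639, cell = 1,
                         f = as.numeric(runif(639) < 0.01))
  bs <- bootstrap_preindustrial(ctrl, 60, n_boot = 40000, seed = 3)
  thr <- ule_threshold(bs, percentile = 99.99)$threshold
  m <- sum(ctrl$f)
  expect_equal(thr, qbinom(0.9999, 60, m / 639))
  # the threshold is an element of the pooled sample
  expect_true(thr %in% bs$samples[1, ])
})

test_that("emergence is strict exceedance and tallies whole cells", {
  thr <- tibble::tibble(cell = 1:3, threshold = c(2, 2, 2))
  expo <- tibble::tibble(run = "r1", pathway = 1.5, birth_year = 2000,
                         cell = 1:3, exposure = c(2, 2.001, 0))
  em <- detect_emergence(expo, thr)
  expect_equal(em$emerged, c(FALSE, TRUE, FALSE))  # E = T does not emerge

  # zero threshold: any positive exposure emerges
  em0 <- detect_emergence(expo, dplyr::mutate(thr, threshold = 0))
  expect_equal(em0$emerged, c(TRUE, TRUE, FALSE))

  B <- tibble::tibble(cell = 1:3, birth_year = 2000,
                      cohort_size = c(100, 200, 400))
  tl <- tally_emerged(em, B)
  expect_equal(tl$emerged_people, 200)  # all-or-nothing per cell
  expect_equal(tl$cohort_people, 700)

  # no emergence and full emergence
  tl0 <- tally_emerged(dplyr::mutate(em, emerged = FALSE), B)
  expect_equal(tl0$emerged_people, 0)
  tl1 <- tally_emerged(dplyr::mutate(em, emerged = TRUE), B)
  expect_equal(tl1$emerged_people, 700)
})

test_that("age of emergence is the first age the trajectory passes T", {
  field <- constant_field(2000:2019, n_cell = 1, f = 1)
  traj <- exposure_trajectory(dplyr::select(field, -run), 2000, 10)
  thr <- tibble::tibble(cell = 1, threshold = 3.5)
  aoe <- age_of_emergence(traj, thr)
  expect_equal(aoe$age_of_emergence, 3)  # cum hits 4 > 3.5 at age 3
  none <- age_of_emergence(traj, tibble::tibble(cell = 1, threshold = 99))
  expect_true(is.na(none$age_of_emergence))
})

test_that("cohort fractions conserve counts between country and global", {
  grid <- tibble::tibble(cell = 1:4, country = c(1L, 1L, 2L, 2L))
  B <- tidyr::expand_grid(cell = 1:4, birth_year = 2000) |>
    dplyr::mutate(cohort_size = c(10, 20, 30, 40))
  em <- tidyr::expand_grid(run = c("r1", "r2"), birth_year = 2000,
                           pathway = 1.5, cell = 1:4) |>
    dplyr::mutate(exposure = 1, emerged = cell %in% c(1, 3))
  tl <- tally_emerged(em, B, grid = grid)
  glb <- tl |> dplyr::filter(is.na(country))
  per <- tl |> dplyr::filter(!is.na(country)) |>
    dplyr::group_by(run) |>
    dplyr::summarise(e = sum(emerged_people), t = sum(cohort_people))
  expect_equal(per$e, glb$emerged_people)  # exact conservation
  expect_equal(per$t, glb$cohort_people)

  cf <- cohort_fraction(glb)
  expect_equal(cf$cf, rep(40 / 100, 2))
  sm <- summarize_cohort_fraction(cf)
  expect_equal(sm$cf_mean, 0.4)
  expect_equal(sm$cf_min, sm$cf_max)  # zero spread for identical runs

  # zero totals flagged NA and excluded
  glb0 <- glb |> dplyr::mutate(cohort_people = 0)
  expect_warning(cf0 <- cohort_fraction(glb0), "undefined")
  expect_true(all(is.na(cf0$cf)))
})

test_that("region restriction re-bases the cohort-fraction denominator", {
  # hazard confined to cells 1-2 (half the population)
  fields <- tidyr::expand_grid(run = c("r1", "r2"), year = 2000:2004,
                               cell = 1:4) |>
    dplyr::mutate(f = ifelse(cell <= 2, 0.5, 0))
  mask <- restrict_to_exposed_regions(fields)
  expect_setequal(mask$cell, 1:2)

  B <- tibble::tibble(cell = 1:4, birth_year = 2000,
                      cohort_size = c(25, 25, 25, 25))
  em <- tibble::tibble(run = "r1", birth_year = 2000, cell = 1:4,
                       exposure = 1, emerged = c(TRUE, FALSE, FALSE, FALSE))
  cf_all <- cohort_fraction(tally_emerged(em, B))
  cf_mask <- cohort_fraction(tally_emerged(em, B, region_mask = mask))
  expect_equal(cf_all$cf, 0.25)
  expect_equal(cf_mask$cf, 0.5)  # denominator halves, CF doubles

  # hazard present everywhere leaves CF unchanged
  mask_all <- restrict_to_exposed_regions(dplyr::mutate(fields, f = 0.1))
  cf_same <- cohort_fraction(tally_emerged(em, B, region_mask = mask_all))
  expect_equal(cf_same$cf, cf_all$cf)

  expect_error(restrict_to_exposed_regions(dplyr::mutate(fields, f = 0)),
               "denominator undefined")
})

test_that("ensemble significance: Welch t with exact rank-sum fallback", {
  # identical groups: not significant, flagged degenerate
  s0 <- ensemble_significance(c(1, 1, 1), c(1, 1, 1))
  expect_false(s0$significant)
  expect_equal(s0$method, "degenerate")

  # zero-variance groups that differ: exact rank-sum p = 2/choose(8,4)
  s1 <- ensemble_significance(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(s1$method, "wilcoxon_exact")
  expect_equal(s1$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_true(s1$significant)

  # clearly separated normal groups are significant via Welch t
  set.seed(3)
  s2 <- ensemble_significance(rnorm(6), rnorm(6) + 10)
  expect_equal(s2$method, "welch_t")
  expect_true(s2$significant)

  expect_error(ensemble_significance(1, c(1, 2)), "at least two")
})

test_that("significance test holds its nominal type-I error rate", {
  # same-distribution ensembles: rejection rate ~ 5% +- 2%
  set.seed(97)
  rej <- vapply(seq_len(1000), function(i) {
    ensemble_significance(rnorm(8), rnorm(8))$significant
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("threshold sensitivity levels off beyond the 99.99th percentile", {
  # integer-valued pooled samples of rare events (the regime where the
  # pooled 40,000 sample still resolves the tail): thresholds at 99.99 and
  # 99.999 differ by at most one event in at least 95% of cells
  cfg <- synth_config(n_lat = 4, n_lon = 4, n_countries = 1, p0 = 0.002,
                      control_years = 600, seed = 13)
  ens <- gen_exposure_ensemble(cfg)
  dem <- gen_demographics(cfg)
  le <- interp_life_expectancy(dem$life_expectancy, 1960)
  bs <- bootstrap_preindustrial(ens$control,
                                dplyr::select(le, country, le),
                                n_boot = 10000, seed = 5, grid = ens$grid)
  t1 <- ule_threshold(bs, 99.99)$threshold
  t2 <- ule_threshold(bs, 99.999)$threshold
  expect_gte(mean(abs(t2 - t1) <= 1), 0.95)
})
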