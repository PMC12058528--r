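test_that("lifetime mean GDP per capita averages with the final-year fraction", {
  # constant GDP per capita over the lifetime returns that constant
  gdp <- tidyr::expand_grid(cell = 1, year = 2000:2013) |>
    dplyr::mutate(gdp = 500 * 20)
  pop <- tidyr::expand_grid(cell = 1, year = 2000:2013) |>
    dplyr::mutate(pop = 20)
  out <- lifetime_mean_gdp(gdp, pop, 10, birth_years = 2000)
  expect_equal(out$gdp_pc, 500)

  # 10 for the first half, 30 for the second half of an even lifetime -> 20
  gdp2 <- gdp |> dplyr::mutate(gdp = ifelse(year < 2005, 10 * 20, 30 * 20))
  out2 <- lifetime_mean_gdp(gdp2, pop, 10, birth_years = 2000)
  expect_equal(out2$gdp_pc, 20)

  # copy-forward extension: series ending 2005 at v covers later lifetimes
  gdp3 <- gdp |> dplyr::filter(year <= 2005)
  out3 <- lifetime_mean_gdp(gdp3, pop, 10, birth_years = 2000)
  expect_equal(out3$gdp_pc, 500)

  # zero population with positive GDP flags the cell NA
  pop0 <- pop |> dplyr::mutate(pop = ifelse(year == 2003, 0, pop))
  expect_warning(out4 <- lifetime_mean_gdp(gdp, pop0, 10, birth_years = 2000),
                 "zero population")
  expect_true(is.na(out4$gdp_pc))
})

test_that("population-weighted binning cuts cumulative population at i/k", {
  # uniform population with indicator equal to rank: exact quintiles
  B <- tibble::tibble(cell = 1:10, birth_year = 2020, cohort_size = 1)
  ind <- tibble::tibble(cell = 1:10, value = 1:10)
  bins <- population_weighted_bins(ind, B, k = 5)
  expect_equal(bins$bin, rep(1:5, each = 2))
  # partition: bin populations sum to the total exactly
  expect_equal(sum(bins$cohort_size), 10)

  # hand cumulative-cut trace: populations (1,1,1,1,1,1,4) in ascending
  # indicator order; the boundary cell that reaches each 20% target closes
  # the lower bin, so the pop-4 cell lands whole in bin 4 and bin 5 stays
  # empty: bins (2,2,2,4,0)
  B7 <- tibble::tibble(cell = 1:7, birth_year = 2020,
                       cohort_size = c(1, 1, 1, 1, 1, 1, 4))
  ind7 <- tibble::tibble(cell = 1:7, value = 1:7)
  bins7 <- population_weighted_bins(ind7, B7, k = 5)
  pops <- vapply(1:5, function(b)
    sum(bins7$cohort_size[bins7$bin == b]), numeric(1))
  expect_equal(pops, c(2, 2, 2, 4, 0))

  # rank invariance under strictly monotone transforms of the indicator
  ind_t <- ind |> dplyr::mutate(value = exp(value / 2))
  expect_equal(population_weighted_bins(ind_t, B, k = 5)$bin, bins$bin)

  expect_error(population_weighted_bins(ind7, B7, k = 9), "9 bins")
})

test_that("extreme strata never overlap and hold ~20% of population each", {
  set.seed(71)
  B <- tibble::tibble(cell = 1:200, birth_year = 2020,
                      cohort_size = runif(200, 0.5, 1.5))
  ind <- tibble::tibble(cell = 1:200, value = rnorm(200))
  bins <- population_weighted_bins(ind, B, k = 5)
  bot <- bins$cell[bins$bin == 1]
  top <- bins$cell[bins$bin == 5]
  expect_length(intersect(bot, top), 0)
  total <- sum(B$cohort_size)
  max_share <- max(B$cohort_size) / total
  for (b in c(1, 5)) {
    share <- sum(bins$cohort_size[bins$bin == b]) / total
    expect_lt(abs(share - 0.2), max_share + 1e-9)
  }
  # "nearly equal" contract across all bins
  pops <- vapply(1:5, function(b)
    sum(bins$cohort_size[bins$bin == b]), numeric(1))
  expect_lte(max(pops) / min(pops), 1 + 5 * max_share)
})

test_that("strata comparison separates groups only when emergence differs", {
  B <- tibble::tibble(cell = 1:100, birth_year = 2020, cohort_size = 1)
  ind <- tibble::tibble(cell = 1:100, value = 1:100)
  bins <- population_weighted_bins(ind, B, k = 5)

  # emergence everywhere: both strata at fraction 1, not significant
  em_all <- tidyr::expand_grid(run = paste0("r", 1:4), pathway = 2.7,
                               birth_year = 2020, cell = 1:100) |>
    dplyr::mutate(exposure = 9, emerged = TRUE)
  st <- strata_ule(em_all, bins)
  expect_equal(st$fraction_mean, c(1, 1))
  expect_false(any(st$significant))

  # emergence concentrated in the top stratum is detected
  set.seed(5)
  em_top <- em_all |>
    dplyr::mutate(emerged = cell > 80 & runif(dplyr::n()) < 0.9)
  st2 <- strata_ule(em_top, bins)
  expect_gt(st2$fraction_mean[st2$stratum == 5],
            st2$fraction_mean[st2$stratum == 1])
  expect_true(all(st2$significant))

  expect_error(strata_ule(em_all, bins, strata = c(1L, 7L)), "empty")
})

test_that("strata are null-calibrated when emergence ignores the indicator", {
  # emergence independent of the indicator: strata fractions agree within
  # Monte-Carlo noise and the test rejects at about the nominal 5% rate
  set.seed(83)
  B <- tibble::tibble(cell = 1:100, birth_year = 2020, cohort_size = 1)
  n_rej <- 0
  n_rep <- 200
  gap <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ind <- tibble::tibble(cell = 1:100, value = rnorm(100))
    bins <- population_weighted_bins(ind, B, k = 5)
    em <- tidyr::expand_grid(run = paste0("r", 1:6), pathway = 2.7,
                             birth_year = 2020, cell = 1:100) |>
      dplyr::mutate(exposure = 1, emerged = runif(dplyr::n()) < 0.5)
    st <- strata_ule(em, bins)
    n_rej <- n_rej + any(st$significant)
    gap[i] <- diff(st$fraction_mean)
  }
  expect_gt(n_rej / n_rep, 0.01)
  expect_lt(n_rej / n_rep, 0.12)
  # mean fraction gap consistent with zero: SE of the mean gap over reps
  expect_lt(abs(mean(gap)), 2 * sd(gap) / sqrt(n_rep))
})
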