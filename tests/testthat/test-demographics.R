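test_that("life expectancy interpolates between block midpoints and adds 5", {
  # constant blocks: LE = 60 + 5 everywhere
  le <- interp_life_expectancy(le_block_table(le = 60))
  expect_true(all(le$le == 65))

  # hand interpolation: blocks 70 (1950-1955) and 72 (1955-1960) have
  # midpoints 1952.5 and 1957.5; at 1955 the interpolant is 71, +5 = 76
  blocks <- le_block_table(le = 72)
  blocks$le[blocks$block_start == 1950] <- 70
  out <- interp_life_expectancy(blocks, birth_years = c(1950, 1955, 2020))
  expect_equal(out$le[out$birth_year == 1955], 76)
  # before the first midpoint: first block value + 5
  expect_equal(out$le[out$birth_year == 1950], 75)
  # beyond the last midpoint (2017.5 not reached at 2020? it is; constant after)
  expect_equal(out$le[out$birth_year == 2020], 77)

  expect_error(
    interp_life_expectancy(dplyr::filter(blocks, block_start != 1980)),
    "missing block.*1980")
})

test_that("population extrapolation is a recursive trailing 10-year mean", {
  pop <- tibble::tibble(cell = 1, year = 2091:2100, pop = 91:100)
  out <- extrapolate_population(pop, to = 2103)
  expect_equal(out$pop[out$year == 2101], 95.5)
  expect_equal(out$pop[out$year == 2102], mean(c(92:100, 95.5)))  # 95.95
  expect_equal(out$pop[out$year == 2102], 95.95)

  # constant population is a fixed point
  popc <- tidyr::expand_grid(cell = 1:3, year = 2091:2100) |>
    dplyr::mutate(pop = 1000)
  outc <- extrapolate_population(popc, to = 2113)
  expect_true(all(outc$pop == 1000))
  expect_setequal(unique(outc$year), 2091:2113)

  expect_error(
    extrapolate_population(tibble::tibble(cell = 1, year = 2095:2100,
                                          pop = 1), to = 2113),
    "10 years")
})

test_that("cohort annualization divides groups by 5 and conserves totals", {
  coh <- cohort_table(size = 5e6)
  ann <- interp_cohort_sizes(coh, years = 1960:2113)
  # each single-year age of a 5-year group carries total / 5
  a04 <- ann |> dplyr::filter(year == 1960, age %in% 0:4)
  expect_true(all(a04$size == 1e6))
  # 100+ maps to age 100 undivided
  a100 <- ann |> dplyr::filter(year == 1960, age == 100)
  expect_equal(a100$size, 5e6)
  # constant tables: constant annual series including the extrapolation
  expect_equal(diff(range(ann$size[ann$age == 7])), 0)

  # round-trip conservation at a table year: re-aggregated 5-year groups
  # reproduce the source totals to 1e-6 relative
  re5 <- ann |> dplyr::filter(year == 2000, age <= 99) |>
    dplyr::mutate(age_group = paste(5 * (age %/% 5), 5 * (age %/% 5) + 4,
                                    sep = "-")) |>
    dplyr::group_by(age_group) |>
    dplyr::summarise(size = sum(size))
  src <- coh |> dplyr::filter(year == 2000, age_group != "100+")
  cmp <- dplyr::left_join(src, re5, by = "age_group")
  expect_true(all(abs(cmp$size.x - cmp$size.y) / cmp$size.x < 1e-6))
})

test_that("cohort extrapolation to 2113 is linear in the last two values", {
  # age group whose annualized size is 100 in 2095 and 110 in 2100:
  # annual slope (110 - 100) / 5 = 2, so 2113 = 110 + 13 * 2 = 136
  coh <- cohort_table(size = 5e6)
  coh$size[coh$age_group == "20-24" & coh$year == 2095] <- 500
  coh$size[coh$age_group == "20-24" & coh$year == 2100] <- 550
  ann <- interp_cohort_sizes(coh, years = 1960:2113)
  expect_equal(ann$size[ann$age == 22 & ann$year == 2095], 100)
  expect_equal(ann$size[ann$age == 22 & ann$year == 2100], 110)
  expect_equal(ann$size[ann$age == 22 & ann$year == 2113], 136)

  # negative extrapolations clamp to zero with a warning
  coh2 <- cohort_table(size = 5e6)
  coh2$size[coh2$age_group == "0-4" & coh2$year == 2100] <- 1
  expect_warning(ann2 <- interp_cohort_sizes(coh2, years = 2100:2113),
                 "clamped")
  expect_true(all(ann2$size >= 0))
})

test_that("interpolation between anchors never overshoots monotone inputs", {
  coh <- cohort_table(size = 1)
  tab_years <- seq(1950, 2100, 5)
  incr <- stats::setNames(seq_along(tab_years), tab_years)
  coh$size <- incr[as.character(coh$year)]
  ann <- interp_cohort_sizes(coh, years = 1960:2100)
  one_age <- ann |> dplyr::filter(age == 10) |> dplyr::arrange(year)
  expect_true(all(diff(one_age$size) >= 0))
  expect_true(all(one_age$size <= max(incr) / 5 + 1e-12))
})

test_that("grid cohort sizes follow population shares homogeneously", {
  grid <- tibble::tibble(cell = 1:3, lat = 0, lon = 0:2,
                         country = c(1L, 1L, NA))
  pop <- tidyr::expand_grid(cell = 1:3, year = 2019:2021) |>
    dplyr::mutate(pop = dplyr::case_when(cell == 1 ~ 1000, cell == 2 ~ 3000,
                                         TRUE ~ 0))
  coh <- cohort_table(size = 5e6)
  ann <- interp_cohort_sizes(coh, years = 1960:2113)
  B <- cohort_size_at_grid(pop, ann, grid, birth_years = 2020)
  # same country: cohort sizes in exact population ratio 1:3
  expect_equal(B$cohort_size[B$cell == 2] / B$cohort_size[B$cell == 1], 3)
  # arithmetic: share of age 0 in 2020 times population
  share0 <- ann$share[ann$year == 2020 & ann$age == 0]
  expect_equal(B$cohort_size[B$cell == 1], 1000 * share0)

  # zero share gives zero cohort
  ann0 <- ann |> dplyr::mutate(share = ifelse(age == 0, 0, share))
  B0 <- cohort_size_at_grid(pop, ann0, grid, birth_years = 2020)
  expect_true(all(B0$cohort_size == 0))

  # populated cell without a country is a consistency error
  pop_bad <- pop |> dplyr::mutate(pop = ifelse(cell == 3, 10, pop))
  expect_error(cohort_size_at_grid(pop_bad, ann, grid, birth_years = 2020),
               "no country")
  # country missing from the tables is a consistency error
  ann_m <- ann |> dplyr::mutate(country = 2)
  expect_error(cohort_size_at_grid(pop, ann_m, grid, birth_years = 2020),
               "absent from the cohort tables")
})

test_that("study-like configs keep the final analysis year within 2113", {
  cfg <- synth_config(n_lat = 3, n_lon = 3, n_countries = 2, seed = 9)
  dem <- gen_demographics(cfg)
  le <- interp_life_expectancy(dem$life_expectancy, birth_years = 2020)
  expect_true(all(2020 + ceiling(le$le) <= 2113))
})
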