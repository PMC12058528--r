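#' Lifetime mean GDP per capita per birth cohort
#'
#' Per grid cell and birth year, the mean over the cohort's lifetime years
#' of cell GDP divided by cell population, with the final year weighted by
#' its lived fraction. The GDP series is first extended to the end of the
#' longest lifetime by copying its final year; population must already
#' cover the lifetime (see [extrapolate_population()]). Cells with zero
#' population but positive GDP in a lifetime year are flagged and excluded
#' (NA).
#'
#' @param gdp Tibble `cell`, `year`, `gdp` (total cell GDP, currency).
#' @param population Tibble `cell`, `year`, `pop` covering all lifetime
#'   years.
#' @param life_expectancy Scalar or tibble `country`, `birth_year`, `le`
#'   (requires `grid`).
#' @param grid Optional tibble `cell`, `country`.
#' @param birth_years Birth years to evaluate (default 1960-2020).
#' @return Tibble: `cell`, `birth_year`, `gdp_pc` (lifetime mean GDP per
#'   capita).
#' @export
lifetime_mean_gdp <- function(gdp, population, life_expectancy, grid = NULL,
                              birth_years = 1960:2020) {
  stop_if_missing_cols(gdp, c("cell", "year", "gdp"), "GDP series")
  stop_if_missing_cols(population, c("cell", "year", "pop"), "population")

  le_for <- function(b) {
    if (is.numeric(life_expectancy) && length(life_expectancy) == 1) {
      cells <- unique(gdp$cell)
      return(tibble(cell = cells, le = life_expectancy))
    }
    stop_if_missing_cols(life_expectancy, c("country", "birth_year", "le"),
                         "life expectancy")
    if (is.null(grid)) abort("lifetime_mean_gdp(): per-country life expectancy needs `grid`.")
    grid |>
      filter(!is.na(.data$country)) |>
      inner_join(filter(life_expectancy, .data$birth_year == b),
                 by = "country") |>
      select("cell", "le")
  }

  # copy-forward extension of the GDP series to the last year needed
  max_le <- if (is.numeric(life_expectancy)) life_expectancy else
    max(life_expectancy$le)
  last_need <- max(birth_years) + ceiling(max_le)
  last_have <- max(gdp$year)
  if (last_have < last_need) {
    final <- gdp |> filter(.data$year == last_have)
    gdp <- bind_rows(gdp, purrr::map_dfr((last_have + 1):last_need,
                                         function(y) mutate(final, year = y)))
  }

  zero_pop <- FALSE
  out <- purrr::map_dfr(birth_years, function(b) {
    le_tbl <- le_for(b)
    purrr::map_dfr(unique(le_tbl$le), function(L) {
      w <- lifetime_weights(b, L)
      cells_le <- le_tbl$cell[le_tbl$le == L]
      d <- gdp |>
        filter(.data$cell %in% cells_le, .data$year %in% w$year) |>
        inner_join(select(population, "cell", "year", "pop"),
                   by = c("cell", "year")) |>
        inner_join(w, by = "year")
      bad <- d$pop <= 0 & d$gdp > 0
      if (any(bad)) {
        zero_pop <<- TRUE
        d$gdp[bad] <- NA_real_
      }
      d |>
        group_by(.data$cell) |>
        summarise(gdp_pc = sum(.data$weight * .data$gdp / .data$pop) /
                    sum(.data$weight), .groups = "drop") |>
        mutate(birth_year = b)
    })
  })
  if (zero_pop) {
    warn("lifetime_mean_gdp(): cells with zero population but positive GDP flagged NA and excluded.")
  }
  select(out, "cell", "birth_year", "gdp_pc")
}

#' Population-weighted quantile bins of a vulnerability indicator
#'
#' Cells are ranked by the indicator (ties broken by cell index, so the
#' binning is invariant under strictly monotone transforms) and cut into
#' `k` groups of nearly equal cohort population: walking the ranked cells,
#' a bin closes at the first cell whose cumulative population reaches
#' `i/k` of the total, that boundary cell included in the lower bin. Cells
#' are never split, so bin populations are only approximately equal.
#'
#' @param indicator Tibble `cell`, `value` (optionally a `birth_year`
#'   column, binned separately per year).
#' @param cohort_sizes Tibble `cell`, `birth_year`, `cohort_size` — the
#'   population weights for the matching year.
#' @param k Number of bins (default 5, i.e. 20% quantile ranges).
#' @param birth_years Birth years to bin (default: all in `cohort_sizes`,
#'   or in the indicator if it carries `birth_year`).
#' @return Tibble: `birth_year`, `cell`, `bin` (1 = lowest indicator
#'   values), `cohort_size`.
#' @export
population_weighted_bins <- function(indicator, cohort_sizes, k = 5L,
                                     birth_years = NULL) {
  stop_if_missing_cols(indicator, c("cell", "value"), "indicator")
  stop_if_missing_cols(cohort_sizes, c("cell", "birth_year", "cohort_size"),
                       "cohort sizes")
  per_year <- "birth_year" %in% names(indicator)
  if (is.null(birth_years)) {
    birth_years <- if (per_year) sort(unique(indicator$birth_year)) else
      sort(unique(cohort_sizes$birth_year))
  }
  purrr::map_dfr(birth_years, function(b) {
    ind <- if (per_year) filter(indicator, .data$birth_year == b) else indicator
    d <- cohort_sizes |>
      filter(.data$birth_year == b, .data$cohort_size > 0) |>
      inner_join(select(ind, "cell", "value"), by = "cell") |>
      filter(!is.na(.data$value)) |>
      arrange(.data$value, .data$cell)
    if (nrow(d) < k) {
      abort(sprintf(
        "population_weighted_bins(): only %d populated cells for birth year %d but k = %d bins requested.",
        nrow(d), b, k))
    }
    total <- sum(d$cohort_size)
    cum <- cumsum(d$cohort_size)
    bin <- integer(nrow(d))
    j <- 1L
    for (i in seq_len(nrow(d))) {
      bin[i] <- j
      if (cum[i] >= j / k * total - 1e-9 * total && j < k) j <- j + 1L
    }
    tibble(birth_year = b, cell = d$cell, bin = bin,
           cohort_size = d$cohort_size)
  })
}

#' Unprecedented exposure across vulnerability strata
#'
#' Compares the incidence of unprecedented lifetime exposure between
#' population-weighted strata of a vulnerability indicator (by default the
#' bottom and top 20%): per birth year, pathway and stratum, the cohort
#' total, the emerged count per ensemble member, the ensemble mean and
#' standard deviation of the emerged fraction, and a pairwise significance
#' test between the two strata across members.
#'
#' @param emergence Output of [detect_emergence()] with `run`, `pathway`,
#'   `birth_year` metadata.
#' @param bins Output of [population_weighted_bins()].
#' @param strata Two bin ids to compare (default `c(1, 5)`: bottom and top
#'   20%).
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `pathway`, `birth_year`, `stratum`, `cohort_people`,
#'   `emerged_mean`, `emerged_sd`, `fraction_mean`, `fraction_sd`,
#'   `p_value`, `significant`, `test`.
#' @export
strata_ule <- function(emergence, bins, strata = c(1L, 5L), alpha = 0.05) {
  stop_if_missing_cols(emergence, c("cell", "birth_year", "emerged", "run"),
                       "emergence")
  stop_if_missing_cols(bins, c("cell", "birth_year", "bin", "cohort_size"),
                       "bins")
  sel <- bins |> filter(.data$bin %in% strata)
  keys <- intersect(c("pathway", "birth_year"), names(emergence))
  emergence <- emergence |>
    filter(.data$birth_year %in% unique(sel$birth_year))
  joined <- emergence |>
    inner_join(sel, by = c("cell", "birth_year"))
  empty <- tidyr::expand_grid(
    bin = strata,
    distinct(emergence, across(dplyr::all_of(keys)))) |>
    anti_join(distinct(joined, .data$bin,
                       across(dplyr::all_of(keys))),
              by = c("bin", keys))
  if (nrow(empty) > 0) {
    abort(sprintf("strata_ule(): stratum %d is empty for birth year %s.",
                  empty$bin[1], format(empty$birth_year[1])))
  }
  per_run <- joined |>
    group_by(across(dplyr::all_of(c(keys, "bin", "run")))) |>
    summarise(cohort_people = sum(.data$cohort_size),
              emerged_people = sum(.data$cohort_size[.data$emerged]),
              .groups = "drop") |>
    mutate(fraction = .data$emerged_people / .data$cohort_people)

  stats <- per_run |>
    group_by(across(dplyr::all_of(c(keys, "bin")))) |>
    summarise(cohort_people = .data$cohort_people[1],
              emerged_mean = mean(.data$emerged_people),
              emerged_sd = sd(.data$emerged_people),
              fraction_mean = mean(.data$fraction),
              fraction_sd = sd(.data$fraction), .groups = "drop")

  tests <- per_run |>
    group_by(across(dplyr::all_of(keys))) |>
    group_modify(function(d, key) {
      x <- d$fraction[d$bin == strata[1]]
      y <- d$fraction[d$bin == strata[2]]
      tst <- ensemble_significance(x, y, alpha = alpha)
      tibble(p_value = tst$p_value, significant = tst$significant,
             test = tst$method)
    }) |>
    ungroup()

  stats |>
    left_join(tests, by = keys) |>
    rename(stratum = "bin")
}
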