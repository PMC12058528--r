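#' Annualize country life expectancy from 5-year blocks
#'
#' Life expectancy of 5-year-olds is reported per country in 5-year blocks
#' (1950-1955 .. 2015-2020). Block values are taken as representative of the
#' block midpoint and linearly interpolated to annual birth years; outside
#' the outermost midpoints the nearest block value is held constant. After
#' interpolation 5 years are added, converting life expectancy of 5-year-olds
#' into life expectancy since birth.
#'
#' @param le_blocks Tibble with columns `country`, `block_start`, `le`
#'   (optionally `block_end`), covering blocks starting 1950, 1955, ..., 2015
#'   for every country.
#' @param birth_years Birth years to evaluate (default 1960-2020).
#' @return Tibble: `country`, `birth_year`, `le` (years since birth).
#' @export
#' @examples
#' blocks <- tibble::tibble(country = 1, block_start = seq(1950, 2015, 5),
#'                          le = 60)
#' interp_life_expectancy(blocks)  # all 65
interp_life_expectancy <- function(le_blocks, birth_years = 1960:2020) {
  stop_if_missing_cols(le_blocks, c("country", "block_start", "le"),
                       "life-expectancy table")
  required <- seq(1950, 2015, by = 5)
  le_blocks |>
    group_by(.data$country) |>
    group_modify(function(d, key) {
      miss <- setdiff(required, d$block_start)
      if (length(miss) > 0) {
        abort(sprintf(
          "interp_life_expectancy(): country %s is missing block(s) starting %s.",
          format(key$country), paste(miss, collapse = ", ")))
      }
      d <- arrange(d, .data$block_start)
      mid <- d$block_start + 2.5
      tibble(birth_year = birth_years,
             le = approx(mid, d$le, xout = birth_years, rule = 2)$y + 5)
    }) |>
    ungroup()
}

#' Extend gridded population totals beyond 2100 by trailing means
#'
#' Each year beyond 2100 is filled, per grid cell, with the mean of the
#' preceding 10 years, recursively: 2101 is the mean of 2091-2100, 2102 the
#' mean of 2092-2101, and so on.
#'
#' @param population Tibble with columns `cell`, `year`, `pop`, annual and
#'   contiguous through 2100 (at least the 10 years 2091-2100 must be
#'   present).
#' @param to Final year to fill (default 2113).
#' @return The input with rows appended for 2101..`to`.
#' @export
#' @examples
#' pop <- tibble::tibble(cell = 1, year = 2091:2100, pop = 91:100)
#' tail(extrapolate_population(pop, to = 2102))  # 95.5 then 95.95
extrapolate_population <- function(population, to = 2113) {
  stop_if_missing_cols(population, c("cell", "year", "pop"), "population grid")
  last <- max(population$year)
  if (last >= to) return(population)
  need <- (last - 9):last
  wide <- population |>
    filter(.data$year %in% need) |>
    tidyr::pivot_wider(names_from = "year", values_from = "pop")
  if (!all(as.character(need) %in% names(wide)) ||
      anyNA(wide[as.character(need)])) {
    abort(sprintf(
      "extrapolate_population(): need the 10 years %d-%d for every cell.",
      min(need), max(need)))
  }
  m <- as.matrix(wide[as.character(need)])
  new_years <- (last + 1):to
  filled <- matrix(0, nrow(m), length(new_years))
  buf <- m
  for (j in seq_along(new_years)) {
    filled[, j] <- rowMeans(buf)
    buf <- cbind(buf[, -1, drop = FALSE], filled[, j])
  }
  extra <- tibble(
    cell = rep(wide$cell, times = length(new_years)),
    year = rep(new_years, each = nrow(wide)),
    pop = as.numeric(filled)
  )
  bind_rows(population, extra) |> arrange(.data$cell, .data$year)
}

#' Annualize cohort sizes from 5-year tables
#'
#' Cohort tables give country population every 5 years (1950-2100) per
#' 5-year age group (0-4 .. 95-99, 100+). Each 5-year group total is split
#' as total/5 across its five single-year ages (100+ maps to single age 100
#' undivided), annual values are linearly interpolated between table years,
#' and the resulting annual series is linearly extrapolated to `to` from its
#' last two values, clamping negatives to zero with a warning. Relative
#' shares are computed against the interpolated all-age total.
#'
#' @param cohorts Tibble with columns `country`, `year`, `age_group`,
#'   `size`; years seq(1950, 2100, 5); age groups `"0-4"` .. `"95-99"`,
#'   `"100+"`.
#' @param years Calendar years of the output (default 1960-2113).
#' @param to Final extrapolation year (default `max(years)`).
#' @return Tibble: `country`, `year`, `age` (0-100), `size`, `share`.
#' @export
interp_cohort_sizes <- function(cohorts, years = 1960:2113, to = max(years)) {
  stop_if_missing_cols(cohorts, c("country", "year", "age_group", "size"),
                       "cohort table")
  table_years <- seq(1950, 2100, by = 5)
  groups5 <- c(paste(seq(0, 95, 5), seq(4, 99, 5), sep = "-"), "100+")
  chk <- cohorts |>
    group_by(.data$country) |>
    summarise(ok_years = all(table_years %in% .data$year),
              ok_ages = all(groups5 %in% .data$age_group), .groups = "drop")
  bad <- chk |> filter(!.data$ok_years | !.data$ok_ages)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "interp_cohort_sizes(): country %s table does not cover 1950-2100 x all age groups.",
      format(bad$country[1])))
  }

  # map 5-year group -> its single-year ages and the division factor
  age_map <- bind_rows(
    purrr::map_dfr(seq(0, 95, 5), function(a0) {
      tibble(age_group = sprintf("%d-%d", a0, a0 + 4), age = a0:(a0 + 4),
             div = 5)
    }),
    tibble(age_group = "100+", age = 100L, div = 1)
  )

  ann_years <- min(table_years):to
  clamped <- FALSE
  out <- cohorts |>
    filter(.data$year %in% table_years) |>
    inner_join(age_map, by = "age_group", relationship = "many-to-many") |>
    mutate(size1 = .data$size / .data$div) |>
    group_by(.data$country, .data$age) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$year)
      v <- approx(d$year, d$size1, xout = ann_years, rule = 1)$y
      beyond <- ann_years > max(d$year)
      if (any(beyond)) {
        n_ann <- sum(!beyond)
        slope <- v[n_ann] - v[n_ann - 1]
        v[beyond] <- v[n_ann] + slope * (ann_years[beyond] - ann_years[n_ann])
        if (any(v[beyond] < 0)) {
          clamped <<- TRUE
          v[beyond] <- pmax(v[beyond], 0)
        }
      }
      tibble(year = ann_years, size = v)
    }) |>
    ungroup()
  if (clamped) {
    warn("interp_cohort_sizes(): negative extrapolated cohort sizes clamped to 0.")
  }
  out |>
    filter(.data$year %in% years) |>
    group_by(.data$country, .data$year) |>
    mutate(share = .data$size / sum(.data$size)) |>
    ungroup() |>
    select("country", "year", "age", "size", "share")
}

#' Grid-scale birth-cohort sizes
#'
#' Downscales country cohort structure to the grid assuming spatially
#' homogeneous cohort representation: the birth-cohort size at a cell is the
#' cell's population in the birth year times the country's relative age-0
#' share for that year.
#'
#' @param population Gridded population tibble (`cell`, `year`, `pop`)
#'   covering the birth years.
#' @param cohort_annual Annualized cohort tibble from
#'   [interp_cohort_sizes()].
#' @param grid Grid tibble with `cell`, `country` (NA = sea).
#' @param birth_years Birth years to evaluate (default 1960-2020).
#' @return Tibble: `cell`, `birth_year`, `cohort_size`.
#' @export
cohort_size_at_grid <- function(population, cohort_annual, grid,
                                birth_years = 1960:2020) {
  stop_if_missing_cols(grid, c("cell", "country"), "grid")
  shares0 <- cohort_annual |>
    filter(.data$age == 0, .data$year %in% birth_years) |>
    select("country", birth_year = "year", "share")
  pop <- population |>
    filter(.data$year %in% birth_years) |>
    rename(birth_year = "year") |>
    left_join(select(grid, "cell", "country"), by = "cell")
  orphan <- pop |>
    filter(is.na(.data$country), .data$pop > 0)
  if (nrow(orphan) > 0) {
    abort(sprintf(
      "cohort_size_at_grid(): cell %d has population but no country assignment.",
      orphan$cell[1]))
  }
  pop <- pop |> filter(!is.na(.data$country))
  missing_c <- setdiff(unique(pop$country), unique(shares0$country))
  if (length(missing_c) > 0) {
    abort(sprintf(
      "cohort_size_at_grid(): country %s in the mask is absent from the cohort tables.",
      format(missing_c[1])))
  }
  pop |>
    inner_join(shares0, by = c("country", "birth_year")) |>
    mutate(cohort_size = .data$pop * .data$share) |>
    select("cell", "birth_year", "cohort_size")
}
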