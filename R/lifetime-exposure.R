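#' Event occurrence from an indicator field with localized thresholds
#'
#' Generic localized-percentile occurrence operator: per grid cell, the
#' threshold is the empirical (nearest-rank) q-th percentile of the cell's
#' pre-industrial control indicator; an event occurs in a year when the
#' indicator lies strictly above that threshold.
#'
#' @param indicator Tibble `cell`, `year`, `value` — the projected
#'   indicator (e.g. a heat magnitude index).
#' @param control Tibble `cell`, `year`, `value` — the stationary
#'   pre-industrial control of the same indicator.
#' @param q Percentile in (0, 100); the control must hold at least
#'   `1 / (1 - q/100)` years.
#' @return Tibble: `cell`, `year`, `occurred` (logical), `threshold`.
#' @export
occurrence_from_indicator <- function(indicator, control, q = 99) {
  stop_if_missing_cols(indicator, c("cell", "year", "value"), "indicator")
  stop_if_missing_cols(control, c("cell", "year", "value"), "control")
  need <- ceiling(1 / (1 - q / 100))
  thr <- control |>
    group_by(.data$cell) |>
    summarise(n_control = n(),
              threshold = nearest_rank_percentile(.data$value, q),
              .groups = "drop")
  short <- thr |> filter(.data$n_control < need)
  if (nrow(short) > 0) {
    abort(sprintf(
      "occurrence_from_indicator(): control of %d years at cell %d is too short for the %.4g-th percentile (need >= %d).",
      short$n_control[1], short$cell[1], q, need))
  }
  indicator |>
    inner_join(select(thr, "cell", "threshold"), by = "cell") |>
    mutate(occurred = .data$value > .data$threshold) |>
    select("cell", "year", "occurred", "threshold")
}

# lifetime year weights of a cohort born in year b with life expectancy L:
# full weight for years b .. b+floor(L)-1, the lived fraction for b+floor(L)
lifetime_weights <- function(birth_year, L) {
  fl <- floor(L)
  frac <- L - fl
  yrs <- birth_year:(birth_year + fl - 1)
  w <- rep(1, fl)
  if (frac > 1e-12) {
    yrs <- c(yrs, birth_year + fl)
    w <- c(w, frac)
  }
  tibble(year = yrs, weight = w)
}

#' Cumulative lifetime exposure per grid cell
#'
#' Sums annual exposure fractions over a cohort's lifetime: full years
#' `b .. b + floor(L) - 1` plus the final year `b + floor(L)` weighted by
#' the fraction of that year lived, `L - floor(L)`. Life expectancy may be a
#' single number for all cells or a per-country table resolved through the
#' grid's country mask. Years beyond the field's coverage are truncated
#' with a warning.
#'
#' @param field Exposure tibble with columns `year`, `cell`, `f`; any other
#'   columns (`run`, `pathway`, ...) are treated as grouping metadata.
#' @param birth_year Birth year `b`.
#' @param life_expectancy A single life expectancy in years, or a tibble
#'   `country`, `le` (requires `grid`).
#' @param grid Optional tibble `cell`, `country` for per-country life
#'   expectancy.
#' @return Tibble: grouping columns, `cell`, `birth_year`, `exposure`
#'   (event-years).
#' @export
#' @examples
#' f <- tidyr::expand_grid(year = 2000:2002, cell = 1)
#' f$f <- 0.4
#' cumulative_lifetime_exposure(f, 2000, 2.5)  # 0.4 + 0.4 + 0.5*0.4 = 1
cumulative_lifetime_exposure <- function(field, birth_year, life_expectancy,
                                         grid = NULL) {
  stop_if_missing_cols(field, c("year", "cell", "f"), "exposure field")
  meta <- setdiff(names(field), c("year", "cell", "f", "source_year"))
  le_tbl <- resolve_le(field, life_expectancy, grid)
  out <- le_tbl |>
    distinct(.data$le) |>
    purrr::pmap_dfr(function(le) {
      w <- lifetime_weights(birth_year, le)
      covered <- w$year %in% unique(field$year)
      if (!all(covered)) {
        warn(sprintf(
          "cumulative_lifetime_exposure(): field ends before the %d cohort's lifetime (%.2f years); truncating.",
          birth_year, le))
        w <- w[covered, , drop = FALSE]
      }
      cells_le <- le_tbl$cell[le_tbl$le == le]
      field |>
        filter(.data$cell %in% cells_le) |>
        inner_join(w, by = "year") |>
        group_by(across(dplyr::all_of(c(meta, "cell")))) |>
        summarise(exposure = sum(.data$f * .data$weight), .groups = "drop")
    })
  out$birth_year <- birth_year
  out
}

resolve_le <- function(field, life_expectancy, grid) {
  cells <- unique(field$cell)
  if (is.numeric(life_expectancy) && length(life_expectancy) == 1) {
    return(tibble(cell = cells, le = life_expectancy))
  }
  if (is.data.frame(life_expectancy)) {
    stop_if_missing_cols(life_expectancy, c("country", "le"),
                         "life expectancy")
    if (is.null(grid)) {
      abort("cumulative_lifetime_exposure(): per-country life expectancy needs `grid`.")
    }
    tbl <- grid |>
      filter(.data$cell %in% cells, !is.na(.data$country)) |>
      left_join(select(life_expectancy, "country", "le"), by = "country")
    if (anyNA(tbl$le)) {
      abort(sprintf(
        "cumulative_lifetime_exposure(): no life expectancy for country %s.",
        format(tbl$country[which(is.na(tbl$le))[1]])))
    }
    return(select(tbl, "cell", "le"))
  }
  abort("cumulative_lifetime_exposure(): life_expectancy must be a scalar or a country/le tibble.")
}

#' Running cumulative exposure since birth
#'
#' The age-resolved partial sums of the lifetime sum: a non-decreasing
#' trajectory per cell whose final element equals
#' [cumulative_lifetime_exposure()].
#'
#' @inheritParams cumulative_lifetime_exposure
#' @return Tibble: grouping columns, `cell`, `birth_year`, `year`, `age`,
#'   `cum_exposure`.
#' @export
exposure_trajectory <- function(field, birth_year, life_expectancy,
                                grid = NULL) {
  stop_if_missing_cols(field, c("year", "cell", "f"), "exposure field")
  meta <- setdiff(names(field), c("year", "cell", "f", "source_year"))
  le_tbl <- resolve_le(field, life_expectancy, grid)
  out <- le_tbl |>
    distinct(.data$le) |>
    purrr::pmap_dfr(function(le) {
      w <- lifetime_weights(birth_year, le)
      covered <- w$year %in% unique(field$year)
      if (!all(covered)) {
        warn(sprintf(
          "exposure_trajectory(): field ends before the %d cohort's lifetime; truncating.",
          birth_year))
        w <- w[covered, , drop = FALSE]
      }
      cells_le <- le_tbl$cell[le_tbl$le == le]
      field |>
        filter(.data$cell %in% cells_le) |>
        inner_join(w, by = "year") |>
        arrange(.data$year) |>
        group_by(across(dplyr::all_of(c(meta, "cell")))) |>
        mutate(cum_exposure = cumsum(.data$f * .data$weight),
               age = .data$year - birth_year) |>
        ungroup() |>
        select(dplyr::all_of(meta), "cell", "year", "age", "cum_exposure")
    })
  out$birth_year <- birth_year
  out
}
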