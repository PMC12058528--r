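#' Bootstrap pre-industrial lifetime exposures per grid cell
#'
#' For each pre-industrial control run, `n_boot` lifetime exposures are
#' formed by drawing `ceiling(L)` control years iid with replacement
#' (L = 1960 birth-cohort life expectancy of the cell's country) and summing
#' the exposure fractions with the final drawn year weighted by the fraction
#' of the final year lived. Resampled year indices are shared across all
#' cells of a country, producing country-wide maps of lifetime exposure;
#' samples are pooled across control runs per cell.
#'
#' @param control Tibble `run`, `year`, `cell`, `f` — stationary
#'   pre-industrial exposure fractions, one series per run (each at least
#'   239 years).
#' @param le_1960 Life expectancy of the 1960 birth cohort: a single number,
#'   or a tibble `country`, `le` together with `grid`.
#' @param n_boot Bootstrap replicates per control run (default 10,000).
#' @param seed Seed for the resampling streams (one stream per run x
#'   country, derived via [derive_seed()]).
#' @param grid Optional tibble `cell`, `country`.
#' @param percentile Percentile the pooled sample is intended to support;
#'   a warning is issued when the pooled size leaves fewer than 4 expected
#'   sample points beyond it.
#' @return Object of class `"baseline_sample"`: pooled sample matrix
#'   (cells x runs*n_boot) plus settings; see [ule_threshold()].
#' @export
bootstrap_preindustrial <- function(control, le_1960, n_boot = 10000L,
                                    seed = 1L, grid = NULL,
                                    percentile = 99.99) {
  stop_if_missing_cols(control, c("run", "year", "cell", "f"), "control")
  runs <- sort(unique(control$run))
  len_tbl <- control |>
    count(.data$run, .data$cell) |>
    group_by(.data$run) |>
    summarise(n_years = min(.data$n), .groups = "drop")
  if (min(len_tbl$n_years) < 239) {
    warn(sprintf(
      "bootstrap_preindustrial(): a control series has only %d years (< 239).",
      min(len_tbl$n_years)))
  }
  pooled_n <- length(runs) * n_boot
  if (pooled_n * (1 - percentile / 100) < 4) {
    warn(sprintf(
      "bootstrap_preindustrial(): pooled sample of %d leaves < 4 expected points beyond the %.4g-th percentile; threshold may be unreliable.",
      pooled_n, percentile))
  }
  le_tbl <- resolve_le(control, le_1960, grid)
  le_tbl <- arrange(le_tbl, .data$cell)
  cells <- le_tbl$cell
  country_of <- if (is.data.frame(le_1960) && !is.null(grid)) {
    grid$country[match(cells, grid$cell)]
  } else rep(1L, length(cells))

  samples <- matrix(NA_real_, nrow = length(cells), ncol = pooled_n,
                    dimnames = list(cells, NULL))
  for (ri in seq_along(runs)) {
    cr <- control |>
      filter(.data$run == runs[ri], .data$cell %in% cells) |>
      select("cell", "year", "f")
    wide <- cr |> arrange(.data$cell, .data$year) |>
      tidyr::pivot_wider(names_from = "year", values_from = "f") |>
      arrange(.data$cell)
    C <- as.matrix(select(wide, -"cell"))
    rownames(C) <- wide$cell
    n_years <- ncol(C)
    for (cc in unique(country_of)) {
      rows <- which(country_of == cc)
      L <- le_tbl$le[rows[1]]
      fl <- floor(L)
      frac <- L - fl
      set.seed(derive_seed(seed, "bootstrap", runs[ri], cc))
      idx <- matrix(sample.int(n_years, (fl + (frac > 1e-12)) * n_boot,
                               replace = TRUE),
                    ncol = n_boot)
      full_idx <- idx[seq_len(fl), , drop = FALSE]
      if (length(rows) <= 8) {
        # small country blocks: sum the drawn years directly per cell
        S <- matrix(0, length(rows), n_boot)
        for (k in seq_along(rows)) {
          v <- C[rows[k], ]
          S[k, ] <- colSums(matrix(v[full_idx], nrow = fl))
        }
      } else {
        # large blocks: lifetime maps as control-matrix x year-count product
        counts <- matrix(0, n_years, n_boot)
        for (j in seq_len(n_boot)) {
          counts[, j] <- tabulate(full_idx[, j], nbins = n_years)
        }
        S <- C[rows, , drop = FALSE] %*% counts
      }
      if (frac > 1e-12) {
        S <- S + frac * C[rows, idx[fl + 1L, ], drop = FALSE]
      }
      samples[rows, ((ri - 1) * n_boot + 1):(ri * n_boot)] <- S
    }
  }
  structure(list(
    samples = samples, cells = cells, le = le_tbl, runs = runs,
    n_boot = n_boot, seed = seed,
    control_years = len_tbl
  ), class = "baseline_sample")
}

#' @export
print.baseline_sample <- function(x, ...) {
  cat(sprintf(
    "<baseline_sample> %d cells x %d pooled lifetime exposures (%d runs x %d bootstrap)\n",
    nrow(x$samples), ncol(x$samples), length(x$runs), x$n_boot))
  invisible(x)
}

#' Unprecedented-lifetime-exposure threshold per grid cell
#'
#' The nearest-rank empirical percentile (default 99.99th) of each cell's
#' pooled pre-industrial lifetime-exposure sample; by construction the
#' threshold is an element of the pooled sample.
#'
#' @param baseline A [bootstrap_preindustrial()] result.
#' @param percentile Percentile in (0, 100] (default 99.99).
#' @return Tibble: `cell`, `threshold` (event-years).
#' @export
ule_threshold <- function(baseline, percentile = 99.99) {
  stopifnot(inherits(baseline, "baseline_sample"))
  tibble(
    cell = baseline$cells,
    threshold = unname(apply(baseline$samples, 1, nearest_rank_percentile,
                             p = percentile))
  )
}

#' Detect emergence of unprecedented lifetime exposure
#'
#' A cohort at a cell emerges when its lifetime exposure strictly exceeds
#' the cell's pre-industrial threshold (`exposure > threshold`).
#'
#' @param exposure Tibble with columns `cell`, `exposure` (plus any
#'   metadata: `run`, `pathway`, `birth_year`, ...).
#' @param thresholds Tibble `cell`, `threshold`.
#' @return The exposure tibble with `threshold` and logical `emerged`
#'   columns added.
#' @export
detect_emergence <- function(exposure, thresholds) {
  stop_if_missing_cols(exposure, c("cell", "exposure"), "lifetime exposure")
  stop_if_missing_cols(thresholds, c("cell", "threshold"), "thresholds")
  exposure |>
    inner_join(thresholds, by = "cell") |>
    mutate(emerged = .data$exposure > .data$threshold)
}

#' Age of emergence from the running exposure trajectory
#'
#' First age at which the cumulative exposure trajectory strictly exceeds
#' the cell's threshold (NA if it never does).
#'
#' @param trajectory Output of [exposure_trajectory()].
#' @param thresholds Tibble `cell`, `threshold`.
#' @return Tibble: grouping columns, `cell`, `birth_year`,
#'   `age_of_emergence`.
#' @export
age_of_emergence <- function(trajectory, thresholds) {
  stop_if_missing_cols(trajectory, c("cell", "age", "cum_exposure"),
                       "trajectory")
  meta <- setdiff(names(trajectory),
                  c("year", "age", "cum_exposure"))
  trajectory |>
    inner_join(thresholds, by = "cell") |>
    group_by(across(dplyr::all_of(meta))) |>
    summarise(age_of_emergence = {
      hit <- .data$age[.data$cum_exposure > .data$threshold]
      if (length(hit) > 0) min(hit) else NA_real_
    }, .groups = "drop")
}

#' Tally emerged people per birth cohort
#'
#' Emergence is all-or-nothing per cell: when a cell emerges, its entire
#' birth-cohort size counts as emerged even if the summed exposed fractions
#' never covered the whole cell.
#'
#' @param emergence Output of [detect_emergence()] with `birth_year`
#'   metadata.
#' @param cohort_sizes Tibble `cell`, `birth_year`, `cohort_size`.
#' @param grid Optional tibble `cell`, `country`; when given, per-country
#'   tallies are returned alongside (`country = NA` rows are the global
#'   tally).
#' @param region_mask Optional tibble with a `cell` column (e.g. from
#'   [restrict_to_exposed_regions()]); both numerator and denominator are
#'   restricted to these cells.
#' @return Tibble: grouping columns, `birth_year` (and `country` if `grid`
#'   given), `emerged_people`, `cohort_people`.
#' @export
tally_emerged <- function(emergence, cohort_sizes, grid = NULL,
                          region_mask = NULL) {
  stop_if_missing_cols(emergence, c("cell", "birth_year", "emerged"),
                       "emergence")
  stop_if_missing_cols(cohort_sizes, c("cell", "birth_year", "cohort_size"),
                       "cohort sizes")
  joined <- emergence |>
    inner_join(cohort_sizes, by = c("cell", "birth_year"))
  if (!is.null(region_mask)) {
    joined <- semi_join(joined, region_mask, by = "cell")
  }
  meta <- setdiff(names(joined),
                  c("cell", "exposure", "threshold", "emerged",
                    "cohort_size"))
  if (!is.null(grid)) {
    joined <- joined |> left_join(select(grid, "cell", "country"), by = "cell")
    meta_c <- c(meta, "country")
    per_country <- joined |>
      group_by(across(dplyr::all_of(meta_c))) |>
      summarise(emerged_people = sum(.data$cohort_size[.data$emerged]),
                cohort_people = sum(.data$cohort_size), .groups = "drop")
    global <- per_country |>
      group_by(across(dplyr::all_of(meta))) |>
      summarise(emerged_people = sum(.data$emerged_people),
                cohort_people = sum(.data$cohort_people), .groups = "drop") |>
      mutate(country = NA)
    return(bind_rows(per_country, global))
  }
  joined |>
    group_by(across(dplyr::all_of(meta))) |>
    summarise(emerged_people = sum(.data$cohort_size[.data$emerged]),
              cohort_people = sum(.data$cohort_size), .groups = "drop")
}

#' Cohort fraction reaching unprecedented lifetime exposure
#'
#' Per-run cohort fraction: emerged people divided by the total cohort.
#' Zero cohort totals yield an NA fraction, flagged and excluded from
#' ensemble aggregation.
#'
#' @param tallies Output of [tally_emerged()].
#' @return The input with a `cf` column added (class `"ule_cf"`).
#' @export
cohort_fraction <- function(tallies) {
  stop_if_missing_cols(tallies, c("emerged_people", "cohort_people"),
                       "tallies")
  out <- tallies |>
    mutate(cf = ifelse(.data$cohort_people > 0,
                       .data$emerged_people / .data$cohort_people,
                       NA_real_))
  if (anyNA(out$cf)) {
    warn("cohort_fraction(): zero cohort totals produced undefined CF; flagged NA and excluded from aggregation.")
  }
  class(out) <- c("ule_cf", class(out))
  out
}

#' Ensemble statistics of cohort fractions
#'
#' Mean (the headline statistic), median, quartiles and full range of CF
#' across the ensemble members valid for each pathway.
#'
#' @param cf A [cohort_fraction()] result with a `run` column.
#' @return Tibble: `pathway`, `birth_year` (and `country` if present),
#'   `cf_mean`, `cf_median`, `cf_q25`, `cf_q75`, `cf_min`, `cf_max`,
#'   `n_runs`. Class `"ule_cf_summary"`.
#' @export
summarize_cohort_fraction <- function(cf) {
  stop_if_missing_cols(cf, c("cf", "run"), "cohort fractions")
  keys <- intersect(c("hazard", "pathway", "birth_year", "country"),
                    names(cf))
  out <- cf |>
    filter(!is.na(.data$cf)) |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(cf_mean = mean(.data$cf),
              cf_median = median(.data$cf),
              cf_q25 = unname(quantile(.data$cf, 0.25)),
              cf_q75 = unname(quantile(.data$cf, 0.75)),
              cf_min = min(.data$cf), cf_max = max(.data$cf),
              n_runs = n(), .groups = "drop")
  class(out) <- c("ule_cf_summary", class(out))
  out
}

#' Restrict analysis to regions ever exposed to the hazard
#'
#' For hazards confined to parts of the world (tropical cyclones), cohort
#' fractions are re-based on the population of cells exposed at least once
#' across the whole ensemble of exposure projections.
#'
#' @param fields A tibble with columns `cell`, `f` (any number of runs /
#'   scenarios stacked), or a list of such tibbles.
#' @return Tibble with column `cell`: the region mask. Pass as
#'   `region_mask` to [tally_emerged()].
#' @export
restrict_to_exposed_regions <- function(fields) {
  if (is.list(fields) && !is.data.frame(fields)) fields <- bind_rows(fields)
  stop_if_missing_cols(fields, c("cell", "f"), "exposure fields")
  mask <- fields |> filter(.data$f > 0) |> distinct(.data$cell)
  if (nrow(mask) == 0) {
    abort("restrict_to_exposed_regions(): no cell is ever exposed; cohort-fraction denominator undefined.")
  }
  mask
}

#' Compare per-run values between two ensembles
#'
#' Two-sided unequal-variance (Welch) t-test across ensemble members at
#' level `alpha`; when either group has zero variance the test degenerates,
#' so an exact Wilcoxon rank-sum test is used instead; two identical
#' constant groups are reported as not significant with a flag.
#'
#' @param a,b Numeric vectors of per-run values (length >= 2 each).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"ule_test"`: tibble with `method`, `statistic`,
#'   `p_value`, `alpha`, `significant`, `note`.
#' @export
#' @examples
#' ensemble_significance(c(0, 0, 0, 0), c(1, 1, 1, 1))  # exact p = 0.0286
ensemble_significance <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    abort("ensemble_significance(): need at least two values per group.")
  }
  degenerate <- var(a) == 0 && var(b) == 0
  if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
    out <- tibble(method = "degenerate", statistic = NA_real_,
                  p_value = NA_real_, alpha = alpha, significant = FALSE,
                  note = "identical zero-variance groups")
  } else if (var(a) == 0 || var(b) == 0) {
    rs <- exact_ranksum(a, b)
    out <- tibble(method = "wilcoxon_exact",
                  statistic = rs$statistic,
                  p_value = rs$p_value, alpha = alpha,
                  significant = rs$p_value < alpha,
                  note = "zero-variance group; exact rank-sum fallback")
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    out <- tibble(method = "welch_t", statistic = unname(tt$statistic),
                  p_value = tt$p.value, alpha = alpha,
                  significant = tt$p.value < alpha, note = NA_character_)
  }
  class(out) <- c("ule_test", class(out))
  out
}

# Exact two-sided rank-sum test by full enumeration of group assignments,
# using midranks so ties (common in zero-variance ensembles) are handled
# exactly; enumeration is feasible at ensemble sizes (choose(n, k) small).
exact_ranksum <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  if (choose(n, n1) > 1e6) {
    wt <- suppressWarnings(wilcox.test(a, b))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value))
  }
  r <- rank(c(a, b))  # midranks
  s_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  s_all <- colSums(matrix(r[combos], nrow = n1))
  p <- mean(abs(s_all - mu) >= abs(s_obs - mu) - 1e-9)
  list(statistic = s_obs, p_value = p)
}
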