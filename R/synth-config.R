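#' Configuration for a synthetic exposure world
#'
#' Defines a complete synthetic study system: a regular lat-lon grid split
#' into countries, an ensemble of model runs (GCM x impact model x scenario),
#' a per-cell hazard occurrence model, demographic parameters, and
#' vulnerability surfaces. Everything downstream — demographic annualization,
#' GMT pathway resampling, lifetime exposure, baseline emergence, strata —
#' can be exercised against this world with known ground truth.
#'
#' The hazard model is annual Bernoulli occurrence per cell with probability
#' linear in the run's smoothed GMT anomaly, `p(x, t) = clamp(p0(x) +
#' beta(x) * W(t), 0, 1)`, and a fixed exposed area fraction `a(x)` given
#' occurrence. A stationary pre-industrial control (`W = 0`) of
#' `control_years` years accompanies every run.
#'
#' @param n_lat,n_lon Grid dimensions.
#' @param cell_deg Cell size in degrees (default 0.5).
#' @param n_countries Number of countries tiling the land cells.
#' @param years Historical + future simulation years of each run.
#' @param control_years Length of each pre-industrial control, an integer in
#'   `[239, 639]`.
#' @param runs Tibble with columns `run`, `gcm`, `impact_model`, `scenario`
#'   (`scenario` one of `"rcp26"`, `"rcp60"`, `"rcp85"`). Default: four
#'   GCMs, one impact model, scenarios spanning the RCP range.
#' @param hazard Hazard label.
#' @param p0 Baseline annual occurrence probability, scalar or one value per
#'   cell, in `[0, 1]`.
#' @param beta GMT sensitivity of occurrence probability (per degree C),
#'   scalar or per cell, `>= 0`.
#' @param a Exposed area fraction given occurrence, scalar or per cell, in
#'   `(0, 1]`.
#' @param sea_fraction Fraction of cells left unassigned to any country.
#' @param le_start,le_end Country-mean life expectancy of 5-year-olds for the
#'   1950-1955 and 2015-2020 blocks (years); blocks in between are linear.
#' @param le_country_sd Between-country spread added to the block values.
#' @param pop_per_cell Mean baseline population per cell (persons).
#' @param pop_growth Annual relative population growth rate.
#' @param scenario_warming Named end-of-century (2099) warming per scenario
#'   (degrees C above 1850-1900).
#' @param gmt_noise_sd Standard deviation of interannual GMT noise.
#' @param anchor_levels End-of-century warming levels of the anchor GMT
#'   trajectories (sorted ascending, spanning the pathway range).
#' @param vuln_rho Target Spearman correlation between the deprivation index
#'   and baseline GDP per capita (typically negative).
#' @param seed Master seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @return A validated list of class `"synth_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_lat = 4, n_lon = 5, n_countries = 2, seed = 7)
#' cfg$n_cell
synth_config <- function(n_lat = 10, n_lon = 10, cell_deg = 0.5,
                         n_countries = 4,
                         years = 1861:2099,
                         control_years = 439L,
                         runs = NULL,
                         hazard = "heatwave",
                         p0 = 0.01, beta = 0.05, a = 1,
                         sea_fraction = 0,
                         le_start = 60, le_end = 73, le_country_sd = 1.5,
                         pop_per_cell = 1e4, pop_growth = 0.01,
                         scenario_warming = c(rcp26 = 1.6, rcp60 = 2.7,
                                              rcp85 = 4.4),
                         gmt_noise_sd = 0.05,
                         anchor_levels = c(1.5, 2.0, 2.5, 3.0, 3.5),
                         vuln_rho = -0.7,
                         seed = 1L) {
  if (is.null(runs)) {
    runs <- tibble(
      run = paste0("run", 1:4),
      gcm = paste0("gcm", 1:4),
      impact_model = "impact1",
      scenario = c("rcp26", "rcp60", "rcp85", "rcp85")
    )
  }
  stop_if_missing_cols(runs, c("run", "gcm", "impact_model", "scenario"), "runs")
  if (anyDuplicated(runs$run)) abort("synth_config(): duplicate run ids.")
  bad_scen <- setdiff(unique(runs$scenario), names(scenario_warming))
  if (length(bad_scen) > 0) {
    abort(sprintf("synth_config(): scenario(s) without a warming level: %s",
                  paste(bad_scen, collapse = ", ")))
  }
  control_years <- as.integer(control_years)
  if (control_years < 239L || control_years > 639L) {
    abort(sprintf(
      "synth_config(): control_years = %d outside the supported 239-639 range.",
      control_years))
  }
  if (is.unsorted(anchor_levels, strictly = TRUE)) {
    abort("synth_config(): anchor_levels must be strictly ascending.")
  }

  n_cell <- n_lat * n_lon
  expand_par <- function(x, name) {
    if (length(x) == 1) x <- rep(x, n_cell)
    if (length(x) != n_cell) {
      abort(sprintf("synth_config(): '%s' must have length 1 or %d.",
                    name, n_cell))
    }
    x
  }
  p0 <- expand_par(p0, "p0")
  beta <- expand_par(beta, "beta")
  a <- expand_par(a, "a")
  check_range <- function(x, name, lo, hi, lo_open = FALSE) {
    bad <- which(!is.finite(x) | x < lo | x > hi | (lo_open & x <= lo))
    if (length(bad) > 0) {
      abort(sprintf(
        "synth_config(): parameter '%s' invalid at cell %d (value %g).",
        name, bad[1], x[bad[1]]))
    }
  }
  check_range(p0, "p0", 0, 1)
  check_range(beta, "beta", 0, Inf)
  check_range(a, "a", 0, 1, lo_open = TRUE)
  if (sea_fraction < 0 || sea_fraction >= 1) {
    abort("synth_config(): sea_fraction must be in [0, 1).")
  }
  if (n_countries < 1) abort("synth_config(): n_countries must be >= 1.")

  structure(list(
    n_lat = n_lat, n_lon = n_lon, cell_deg = cell_deg, n_cell = n_cell,
    n_countries = as.integer(n_countries),
    years = years, control_years = control_years, runs = runs,
    hazard = hazard, p0 = p0, beta = beta, a = a,
    sea_fraction = sea_fraction,
    le_start = le_start, le_end = le_end, le_country_sd = le_country_sd,
    pop_per_cell = pop_per_cell, pop_growth = pop_growth,
    scenario_warming = scenario_warming, gmt_noise_sd = gmt_noise_sd,
    anchor_levels = anchor_levels, vuln_rho = vuln_rho,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %dx%d grid (%d cells), %d countries, %d runs, hazard '%s'\n",
    x$n_lat, x$n_lon, x$n_cell, x$n_countries, nrow(x$runs), x$hazard))
  cat(sprintf("  run years %d-%d, control %d years, seed %d\n",
              min(x$years), max(x$years), x$control_years, x$seed))
  invisible(x)
}

#' Grid and country mask of a synthetic world
#'
#' Cells are numbered row-major over the lat-lon grid; countries tile the
#' land cells in contiguous index blocks; the trailing `sea_fraction` of
#' cells is left unassigned (`country = NA`).
#'
#' @param cfg A [synth_config()].
#' @return Tibble with columns `cell`, `lat`, `lon`, `country`.
#' @export
gen_grid <- function(cfg) {
  n <- cfg$n_cell
  n_sea <- floor(cfg$sea_fraction * n)
  n_land <- n - n_sea
  country <- c(
    as.integer(ceiling(seq_len(n_land) / (n_land / cfg$n_countries))),
    rep(NA_integer_, n_sea)
  )
  country[country > cfg$n_countries] <- cfg$n_countries
  tibble(
    cell = seq_len(n),
    lat = rep(seq(0, by = cfg$cell_deg, length.out = cfg$n_lat), each = cfg$n_lon),
    lon = rep(seq(0, by = cfg$cell_deg, length.out = cfg$n_lon), times = cfg$n_lat),
    country = country
  )
}
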