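# Deterministic warming backbone shared by runs and anchors: ~0 before 1880,
# reaching 0.3 C in 1960 and 1.2 C in 2020 (anomaly vs 1850-1900), so that
# simulated runs and target pathways agree over the historical period and
# warming-level matching has analogue years to find.
warming_backbone <- function(years) {
  w <- numeric(length(years))
  ramp0 <- years > 1880 & years <= 1960
  w[ramp0] <- 0.3 * (years[ramp0] - 1880) / 80
  hist <- years > 1960 & years <= 2020
  w[hist] <- 0.3 + 0.9 * (years[hist] - 1960) / 60
  w[years > 2020] <- 1.2
  w
}

# Scenario divergence after 2005: run warming rises from the backbone level
# toward its scenario's 2099 target with a mildly convex ramp.
run_gmt_curve <- function(years, end_level) {
  w <- warming_backbone(pmin(years, 2005))
  fut <- years > 2005
  u <- (years[fut] - 2005) / (2099 - 2005)
  w2005 <- 0.3 + 0.9 * 45 / 60
  w[fut] <- w2005 + (end_level - w2005) * u^1.3
  w
}

#' Generate a synthetic exposure ensemble with per-run GMT series
#'
#' For every run in the configuration, draws annual Bernoulli occurrence per
#' grid cell with probability `clamp(p0 + beta * W_s(t), 0, 1)`, where `W_s`
#' is the run's 21-year-smoothed GMT anomaly, and records exposure fraction
#' `a * occurrence`. Each run also gets a stationary pre-industrial control
#' (`W = 0`, occurrence probability `p0`) of `cfg$control_years` years.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `"exposure_ensemble"` with elements
#'   `exposure` (tibble: `run`, `scenario`, `year`, `cell`, `f`),
#'   `control` (tibble: `run`, `year`, `cell`, `f`; years are nominal
#'   control years numbered 1..n),
#'   `gmt` (tibble: `run`, `scenario`, `year`, `gmt`),
#'   `grid`, `params` (tibble: `cell`, `p0`, `beta`, `a`), `hazard`, `cfg`.
#' @export
#' @examples
#' ens <- gen_exposure_ensemble(synth_config(n_lat = 3, n_lon = 3, seed = 1))
#' dplyr::count(ens$exposure, run)
gen_exposure_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- gen_grid(cfg)
  n_cell <- cfg$n_cell
  years <- cfg$years
  n_yr <- length(years)

  gmt <- purrr::pmap_dfr(cfg$runs, function(run, gcm, impact_model, scenario) {
    end_level <- cfg$scenario_warming[[scenario]]
    set.seed(derive_seed(cfg$seed, "gmt", run))
    noise <- as.numeric(stats::filter(rnorm(n_yr, 0, cfg$gmt_noise_sd),
                                      0.5, method = "recursive"))
    tibble(run = run, scenario = scenario, year = years,
           gmt = run_gmt_curve(years, end_level) + noise)
  })

  draw_field <- function(p_by_year, seed_tag, run, yrs) {
    # p_by_year: matrix n_cell x n_years of occurrence probabilities
    set.seed(derive_seed(cfg$seed, seed_tag, run))
    occ <- matrix(runif(length(p_by_year)) < p_by_year, nrow = nrow(p_by_year))
    tibble(
      run = run,
      year = rep(yrs, each = n_cell),
      cell = rep(seq_len(n_cell), times = length(yrs)),
      f = as.numeric(occ) * rep(cfg$a, times = length(yrs))
    )
  }

  exposure <- purrr::map_dfr(cfg$runs$run, function(r) {
    w <- gmt$gmt[gmt$run == r]
    ws <- roll_mean_shrink(w, 21L)
    p <- clamp01(outer(cfg$p0, rep(1, n_yr)) + outer(cfg$beta, ws))
    out <- draw_field(p, "exposure", r, years)
    out$scenario <- cfg$runs$scenario[cfg$runs$run == r]
    out[, c("run", "scenario", "year", "cell", "f")]
  })

  control <- purrr::map_dfr(cfg$runs$run, function(r) {
    p <- matrix(cfg$p0, nrow = n_cell, ncol = cfg$control_years)
    draw_field(p, "control", r, seq_len(cfg$control_years))
  })

  structure(list(
    exposure = exposure, control = control, gmt = gmt, grid = grid,
    params = tibble(cell = seq_len(n_cell), p0 = cfg$p0, beta = cfg$beta,
                    a = cfg$a),
    hazard = cfg$hazard, cfg = cfg
  ), class = "exposure_ensemble")
}

#' @export
print.exposure_ensemble <- function(x, ...) {
  cat(sprintf(
    "<exposure_ensemble> hazard '%s': %d runs x %d cells, run years %d-%d, control %d years\n",
    x$hazard, nrow(x$cfg$runs), x$cfg$n_cell,
    min(x$cfg$years), max(x$cfg$years), x$cfg$control_years))
  invisible(x)
}

#' Generate synthetic demographic tables
#'
#' Produces tables structurally identical to the study-style sources so the
#' demographics module consumes synthetic and real data through one reader:
#' country life expectancy of 5-year-olds in 5-year blocks (1950-1955 ..
#' 2015-2020), country cohort sizes every 5 years (1950-2100) for 5-year age
#' groups (0-4 .. 95-99, 100+), and gridded annual population totals
#' (1860-2100).
#'
#' @param cfg A [synth_config()].
#' @param constant If `TRUE`, all time trends are switched off (constant
#'   life expectancy, cohort sizes and population), which makes every
#'   downstream interpolation a fixed point — useful for testing.
#' @return List with elements `life_expectancy` (tibble: `country`,
#'   `block_start`, `block_end`, `le`), `cohorts` (tibble: `country`,
#'   `year`, `age_group`, `size`), `population` (tibble: `cell`, `year`,
#'   `pop`), `grid`.
#' @export
gen_demographics <- function(cfg, constant = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- gen_grid(cfg)
  countries <- seq_len(cfg$n_countries)
  set.seed(derive_seed(cfg$seed, "demographics"))
  le_offset <- rnorm(cfg$n_countries, 0, cfg$le_country_sd)

  block_start <- seq(1950, 2015, by = 5)
  trend <- if (constant) rep(0, length(block_start)) else
    (cfg$le_end - cfg$le_start) * (block_start - 1950) / 65
  life_expectancy <- tidyr::expand_grid(country = countries,
                                        block_start = block_start) |>
    mutate(block_end = .data$block_start + 5,
           le = cfg$le_start + trend[match(.data$block_start, block_start)] +
             le_offset[.data$country])

  # Cohort sizes: country totals grow geometrically; age structure is a
  # smooth geometric decay over the 21 age groups, constant in time.
  age_groups <- c(paste(seq(0, 95, 5), seq(4, 99, 5), sep = "-"), "100+")
  age_w <- exp(-0.15 * seq(0, 20))
  age_w <- age_w / sum(age_w)
  table_years <- seq(1950, 2100, by = 5)
  country_pop0 <- cfg$pop_per_cell *
    as.numeric(table(grid$country[!is.na(grid$country)]))
  growth <- if (constant) 0 else cfg$pop_growth
  cohorts <- tidyr::expand_grid(country = countries, year = table_years) |>
    mutate(total = country_pop0[.data$country] *
             (1 + growth)^(.data$year - 1950)) |>
    tidyr::expand_grid(age_group = age_groups) |>
    mutate(size = .data$total * age_w[match(.data$age_group, age_groups)]) |>
    select("country", "year", "age_group", "size")

  # Gridded population: fixed lognormal cell weights within a country times
  # the country growth curve; sea cells carry zero population.
  set.seed(derive_seed(cfg$seed, "population"))
  cell_w <- exp(rnorm(cfg$n_cell, 0, 0.5))
  cell_w[is.na(grid$country)] <- 0
  pop_years <- 1860:2100
  population <- tibble(
    cell = rep(grid$cell, times = length(pop_years)),
    year = rep(pop_years, each = cfg$n_cell),
    pop = rep(cell_w * cfg$pop_per_cell, times = length(pop_years)) *
      (1 + growth)^(rep(pop_years, each = cfg$n_cell) - 1950)
  )

  list(life_expectancy = life_expectancy, cohorts = cohorts,
       population = population, grid = grid)
}

#' Generate synthetic vulnerability surfaces
#'
#' A gridded deprivation index on the 0-100 scale (higher = more deprived)
#' and a gridded annual GDP series (strictly positive), with the rank
#' correlation between deprivation and baseline GDP per capita controlled by
#' `cfg$vuln_rho` through a Gaussian copula. `vuln_rho = -1` forces
#' deprivation to be the exact reverse ranking of GDP per capita.
#'
#' @param cfg A [synth_config()].
#' @param population Optional gridded population tibble (`cell`, `year`,
#'   `pop`) used to scale cell GDP; defaults to [gen_demographics()] output.
#' @return List with `deprivation` (tibble: `cell`, `grdi`), `gdp` (tibble:
#'   `cell`, `year`, `gdp`), and the per-cell baseline `gdp_pc_base`.
#' @export
gen_vulnerability <- function(cfg, population = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(population)) population <- gen_demographics(cfg)$population
  set.seed(derive_seed(cfg$seed, "vulnerability"))
  n <- cfg$n_cell
  gdp_pc <- exp(rnorm(n, log(1e4), 0.6))

  rho <- cfg$vuln_rho
  z_g <- qnorm(rank(gdp_pc, ties.method = "first") / (n + 1))
  if (abs(rho) >= 1 - 1e-12) {
    z_d <- sign(rho) * z_g
  } else {
    # Gaussian-copula correlation giving the target Spearman rho
    r <- 2 * sin(pi * rho / 6)
    z_d <- r * z_g + sqrt(1 - r^2) * rnorm(n)
  }
  grdi <- 100 * (rank(z_d, ties.method = "first") - 0.5) / n

  gdp <- population |>
    mutate(gdp = .data$pop * gdp_pc[.data$cell] *
             (1 + 0.005)^(.data$year - 1950)) |>
    mutate(gdp = pmax(.data$gdp, 1e-6)) |>
    select("cell", "year", "gdp")

  list(deprivation = tibble(cell = seq_len(n), grdi = grdi),
       gdp = gdp, gdp_pc_base = gdp_pc)
}

#' Generate anchor GMT trajectories
#'
#' Deterministic smooth trajectories sharing the historical warming backbone
#' and fanning out after 2020 to reach each configured anchor level exactly
#' in 2100, constant thereafter. Series are monotone non-decreasing in time
#' and pointwise non-decreasing in anchor level, so low pathways never
#' overshoot.
#'
#' @param cfg A [synth_config()], or a numeric vector of anchor levels.
#' @param years Years of the trajectories (default 1960-2113).
#' @return Tibble with columns `anchor` (nominal 2100 level), `year`, `gmt`.
#' @export
#' @examples
#' anchors <- gen_gmt_anchors(c(1.5, 2.5, 3.5))
#' dplyr::filter(anchors, year == 2100)
gen_gmt_anchors <- function(cfg, years = 1960:2113) {
  levels <- if (inherits(cfg, "synth_config")) cfg$anchor_levels else cfg
  if (length(levels) < 1) abort("gen_gmt_anchors(): need at least one level.")
  if (is.unsorted(levels, strictly = TRUE)) {
    abort("gen_gmt_anchors(): anchor levels must be strictly ascending (no duplicates).")
  }
  if (any(levels < 1.2)) {
    abort("gen_gmt_anchors(): anchor levels below the 2020 backbone (1.2 C) are not supported.")
  }
  base <- warming_backbone(pmin(years, 2020))
  purrr::map_dfr(levels, function(lv) {
    u <- pmin(pmax((years - 2020) / 80, 0), 1)
    tibble(anchor = lv, year = years, gmt = base + (lv - 1.2) * u)
  })
}
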