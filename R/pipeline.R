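#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: the synthetic world
#' (or pre-generated inputs), the birth-year range, pathway construction,
#' the warming-level matching constraint, bootstrap settings and optional
#' vulnerability stratification.
#'
#' @param synthetic Arguments passed to [synth_config()], or an existing
#'   `synth_config`.
#' @param inputs Optional pre-generated inputs (a list with `ensemble`,
#'   `demographics`, and optionally `vulnerability`); exactly one of
#'   `synthetic` / `inputs` is used.
#' @param birth_years Birth cohorts analysed (default 1960-2020).
#' @param pathway_lo,pathway_hi,pathway_step Target pathway levels.
#' @param window Rolling-mean window for GMT smoothing (years, default 21).
#' @param constraint Maximum warming-level discrepancy for a valid mapping
#'   (degC, default 0.2).
#' @param n_boot Bootstrap replicates per control run (default 10,000).
#' @param percentile Emergence-threshold percentile (default 99.99; must be
#'   in (50, 100)).
#' @param strata Optional list: `indicator` ("deprivation" or "gdp"),
#'   `k` (bins), `strata` (two bin ids), `pathway` (level at which to
#'   compare), `birth_years`.
#' @param seed Master seed.
#' @return List of class `"ule_config"`.
#' @export
ule_config <- function(synthetic = list(), inputs = NULL,
                       birth_years = 1960:2020,
                       pathway_lo = 1.5, pathway_hi = 3.5, pathway_step = 0.1,
                       window = 21L, constraint = 0.2,
                       n_boot = 10000L, percentile = 99.99,
                       strata = NULL, seed = 1L) {
  if (!is.null(inputs) && length(synthetic) > 0) {
    abort("ule_config(): provide either `synthetic` or `inputs`, not both.")
  }
  if (percentile <= 50 || percentile >= 100) {
    abort("ule_config(): percentile must be in (50, 100).")
  }
  if (is.null(inputs) && !inherits(synthetic, "synth_config")) {
    synthetic$seed <- synthetic$seed %||% seed
    synthetic <- do.call(synth_config, synthetic)
  }
  structure(list(
    synthetic = if (is.null(inputs)) synthetic else NULL,
    inputs = inputs, birth_years = birth_years,
    pathway_lo = pathway_lo, pathway_hi = pathway_hi,
    pathway_step = pathway_step, window = as.integer(window),
    constraint = constraint, n_boot = as.integer(n_boot),
    percentile = percentile, strata = strata, seed = as.integer(seed)
  ), class = "ule_config")
}

#' @rdname ule_config
#' @param path Path to a YAML file whose keys mirror the [ule_config()]
#'   arguments.
#' @export
read_ule_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$birth_years) && length(vals$birth_years) == 2) {
    vals$birth_years <- vals$birth_years[1]:vals$birth_years[2]
  }
  do.call(ule_config, vals)
}

#' Validate pipeline inputs
#'
#' Schema, dimension and range checks on a world (synthetic or read from
#' disk): exposure fractions within [0, 1] (failures name the offending
#' cell and year), contiguous annual time axes, complete cohort tables
#' (failures name country and year), non-negative population, and country
#' mask consistency.
#'
#' @param world List with `ensemble` (an `exposure_ensemble`-like list) and
#'   `demographics` (a [gen_demographics()]-like list).
#' @return Tibble report (`check`, `ok`, `detail`) with attribute `"ok"`;
#'   use `all_ok(report)` to gate on it.
#' @export
validate_inputs <- function(world) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(check = check, ok = ok,
                                            detail = detail)
  }
  ens <- world$ensemble
  dem <- world$demographics

  bad <- ens$exposure |> filter(.data$f < 0 | .data$f > 1)
  add("exposure fractions in [0, 1]", nrow(bad) == 0,
      if (nrow(bad) > 0) sprintf("f = %g at cell %d, year %d (run %s)",
                                 bad$f[1], bad$cell[1], bad$year[1],
                                 bad$run[1]) else "")
  gaps <- ens$exposure |>
    distinct(.data$run, .data$year) |>
    group_by(.data$run) |>
    summarise(contiguous = all(diff(sort(.data$year)) == 1),
              .groups = "drop")
  add("contiguous annual exposure years", all(gaps$contiguous),
      if (!all(gaps$contiguous)) paste("run", gaps$run[!gaps$contiguous][1]) else "")
  ctrl_len <- ens$control |> count(.data$run, .data$cell)
  add("control length >= 239 years", all(ctrl_len$n >= 239),
      if (any(ctrl_len$n < 239)) sprintf("run %s has %d years",
                                         ctrl_len$run[which.min(ctrl_len$n)],
                                         min(ctrl_len$n)) else "")

  groups5 <- c(paste(seq(0, 95, 5), seq(4, 99, 5), sep = "-"), "100+")
  coh <- dem$cohorts |>
    group_by(.data$country, .data$year) |>
    summarise(complete = all(groups5 %in% .data$age_group), .groups = "drop")
  add("cohort tables complete (all age groups)", all(coh$complete),
      if (!all(coh$complete)) {
        i <- which(!coh$complete)[1]
        sprintf("country %s, year %d", format(coh$country[i]), coh$year[i])
      } else "")
  add("population non-negative", all(dem$population$pop >= 0),
      if (any(dem$population$pop < 0))
        sprintf("cell %d", dem$population$cell[which(dem$population$pop < 0)[1]])
      else "")
  mask_countries <- unique(stats::na.omit(dem$grid$country))
  add("every mask country has demographic tables",
      all(mask_countries %in% dem$life_expectancy$country) &&
        all(mask_countries %in% dem$cohorts$country), "")

  report <- bind_rows(checks)
  attr(report, "ok") <- all(report$ok)
  report
}

#' @rdname validate_inputs
#' @param report A report from [validate_inputs()].
#' @export
all_ok <- function(report) isTRUE(attr(report, "ok"))

#' Run the full unprecedented-lifetime-exposure pipeline
#'
#' Orchestrates every stage end-to-end: generate (or take) the input world,
#' validate it, annualize demographics and downscale cohort sizes, build
#' GMT pathways and map each run onto them, resample exposures, accumulate
#' lifetime exposure per birth cohort, bootstrap the pre-industrial
#' baseline and its emergence threshold, detect emergence, tally emerged
#' people into cohort fractions with ensemble statistics, and (optionally)
#' stratify by vulnerability. Pathways for which no run satisfies the
#' warming-discrepancy constraint are reported explicitly as empty
#' ensembles, never as silent missing values.
#'
#' @param config An [ule_config()].
#' @param output_dir Optional directory; when given, CF tables, thresholds,
#'   strata tables, ensemble sizes and a JSON manifest are written there.
#' @param quiet Suppress stage messages.
#' @return List of class `"ule_result"`: `cf` (per-run cohort fractions),
#'   `cf_summary`, `cf_country`, `thresholds`, `emergence`,
#'   `ensemble_sizes`, `empty_pathways`, `strata`, `validation`, `world`,
#'   `demog`, `mapping`, `config`.
#' @export
run_ule_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "ule_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  t0 <- Sys.time()

  # stage: inputs
  if (!is.null(config$inputs)) {
    ens <- config$inputs$ensemble
    dem <- config$inputs$demographics
    vul <- config$inputs$vulnerability
  } else {
    say("[generate] synthetic world (seed %d)", config$seed)
    ens <- gen_exposure_ensemble(config$synthetic)
    dem <- gen_demographics(config$synthetic)
    vul <- if (!is.null(config$strata))
      gen_vulnerability(config$synthetic, population = dem$population)
  }
  grid <- ens$grid

  say("[validate] inputs")
  report <- validate_inputs(list(ensemble = ens, demographics = dem))
  if (!all_ok(report)) {
    bad <- report |> filter(!.data$ok)
    abort(sprintf("run_ule_pipeline(): validation failed at '%s' (%s).",
                  bad$check[1], bad$detail[1]))
  }

  # stage: demographics
  say("[demographics] annualizing tables")
  by_all <- sort(union(config$birth_years, 1960L))
  le_annual <- interp_life_expectancy(dem$life_expectancy, by_all)
  pop <- extrapolate_population(dem$population, to = 2113)
  cohort_annual <- interp_cohort_sizes(dem$cohorts)
  cohort_sizes <- cohort_size_at_grid(pop, cohort_annual, grid,
                                      birth_years = config$birth_years)

  # stage: pathways and mapping
  say("[pathways] building %g-%g degC at %g steps", config$pathway_lo,
      config$pathway_hi, config$pathway_step)
  anchors <- if (!is.null(config$inputs$anchors)) config$inputs$anchors else
    gen_gmt_anchors(if (!is.null(config$synthetic)) config$synthetic else
      stop("anchors required"))
  pathways <- build_pathways(anchors, lo = config$pathway_lo,
                             hi = config$pathway_hi,
                             step = config$pathway_step)
  gmt_s <- smooth_gmt(select(ens$gmt, "run", "year", "gmt"),
                      window = config$window)
  mapping <- map_years(gmt_s, pathways, constraint = config$constraint)
  sizes <- ensemble_sizes(mapping)
  empty <- sizes$pathway[sizes$n_runs == 0]
  for (pw in empty) {
    say("[pathways] EMPTY ENSEMBLE: no run satisfies the %.2f degC constraint for pathway %.1f",
        config$constraint, pw)
  }
  if (length(empty) == length(unique(mapping$pathway))) {
    abort(sprintf(
      "run_ule_pipeline(): empty ensemble at every pathway under the %.2f degC constraint.",
      config$constraint))
  }
  say("[pathways] ensemble sizes: %s",
      paste(sprintf("%.1f:%d", sizes$pathway, sizes$n_runs), collapse = " "))

  # stage: lifetime exposure along pathways
  say("[exposure] resampling and accumulating lifetimes")
  valid <- mapping |> filter(.data$valid)
  resampled <- resample_exposure(
    select(ens$exposure, "run", "year", "cell", "f"), valid)
  le_by <- function(b) {
    le_annual |> filter(.data$birth_year == b) |> select("country", "le")
  }
  exposures <- purrr::map_dfr(config$birth_years, function(b) {
    cumulative_lifetime_exposure(
      select(resampled, "run", "pathway", "year", "cell", "f"),
      b, le_by(b), grid = grid)
  })

  # stage: baseline and threshold
  say("[baseline] bootstrapping %d x %d pre-industrial lifetimes",
      length(unique(ens$control$run)), config$n_boot)
  baseline <- bootstrap_preindustrial(
    ens$control, le_by(1960L), n_boot = config$n_boot,
    seed = derive_seed(config$seed, "baseline"), grid = grid,
    percentile = config$percentile)
  thresholds <- ule_threshold(baseline, percentile = config$percentile)

  # stage: emergence and cohort fractions
  say("[emerge] detecting emergence and tallying cohorts")
  emergence <- detect_emergence(exposures, thresholds)
  tall <- tally_emerged(emergence, cohort_sizes, grid = grid)
  cf_all <- cohort_fraction(tall)
  cf <- cf_all |> filter(is.na(.data$country)) |> select(-"country")
  cf_country <- cf_all |> filter(!is.na(.data$country))
  cf_summary <- summarize_cohort_fraction(cf)

  # stage: strata
  strata_tbl <- NULL
  if (!is.null(config$strata)) {
    st <- config$strata
    say("[strata] %s quantile comparison", st$indicator %||% "deprivation")
    ind <- if ((st$indicator %||% "deprivation") == "gdp") {
      lifetime_mean_gdp(vul$gdp, pop, le_annual, grid = grid,
                        birth_years = st$birth_years %||% config$birth_years) |>
        rename(value = "gdp_pc")
    } else {
      vul$deprivation |> rename(value = "grdi")
    }
    bins <- population_weighted_bins(
      ind, cohort_sizes, k = st$k %||% 5L,
      birth_years = st$birth_years %||% config$birth_years)
    pw_target <- st$pathway %||% max(sizes$pathway[sizes$n_runs >= 2])
    pw_avail <- sizes$pathway[sizes$n_runs >= 2]
    pw_use <- pw_avail[which.min(abs(pw_avail - pw_target))]
    strata_tbl <- strata_ule(filter(emergence, .data$pathway == pw_use),
                             bins, strata = st$strata %||% c(1L, 5L))
  }

  result <- structure(list(
    cf = cf, cf_summary = cf_summary, cf_country = cf_country,
    thresholds = thresholds, emergence = emergence,
    ensemble_sizes = sizes, empty_pathways = empty,
    strata = strata_tbl, validation = report,
    world = list(ensemble = ens, demographics = dem, vulnerability = vul),
    demog = list(le_annual = le_annual, population = pop,
                 cohort_annual = cohort_annual,
                 cohort_sizes = cohort_sizes),
    mapping = mapping, baseline = baseline, config = config
  ), class = "ule_result")

  if (!is.null(output_dir)) write_ule_outputs(result, output_dir)
  say("[done] %.1f s elapsed", as.numeric(difftime(Sys.time(), t0, "secs")))
  result
}

#' @export
print.ule_result <- function(x, ...) {
  cat(sprintf(
    "<ule_result> %d birth years x %d pathways (%d-%d runs per pathway)\n",
    length(unique(x$cf$birth_year)), length(unique(x$cf$pathway)),
    min(x$ensemble_sizes$n_runs), max(x$ensemble_sizes$n_runs)))
  if (length(x$empty_pathways) > 0) {
    cat(sprintf("  empty ensembles at pathway(s): %s\n",
                paste(x$empty_pathways, collapse = ", ")))
  }
  cat("  headline (ensemble-mean CF, last birth year):\n")
  last_by <- max(x$cf_summary$birth_year)
  top <- x$cf_summary |> filter(.data$birth_year == last_by)
  for (i in seq_len(min(5, nrow(top)))) {
    cat(sprintf("    pathway %.1f: CF = %.1f%%\n", top$pathway[i],
                100 * top$cf_mean[i]))
  }
  invisible(x)
}

write_ule_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$cf, file.path(output_dir, "cohort_fraction.csv"))
  readr::write_csv(result$cf_summary,
                   file.path(output_dir, "cohort_fraction_summary.csv"))
  readr::write_csv(result$cf_country,
                   file.path(output_dir, "cohort_fraction_country.csv"))
  readr::write_csv(result$thresholds, file.path(output_dir, "thresholds.csv"))
  sizes <- result$ensemble_sizes |>
    mutate(runs = purrr::map_chr(.data$runs, function(r)
      paste(unlist(r), collapse = ";")))
  readr::write_csv(sizes, file.path(output_dir, "ensemble_sizes.csv"))
  readr::write_csv(select(result$mapping, -dplyr::any_of("discrepancy")) |>
                     distinct(),
                   file.path(output_dir, "year_mapping.csv"))
  if (!is.null(result$strata)) {
    readr::write_csv(result$strata, file.path(output_dir, "strata.csv"))
  }
  cfg <- result$config
  manifest <- list(
    package = "ulexp",
    version = as.character(utils::packageVersion("ulexp")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    settings = list(
      birth_years = range(cfg$birth_years),
      pathway = list(lo = cfg$pathway_lo, hi = cfg$pathway_hi,
                     step = cfg$pathway_step),
      smoothing_window_years = cfg$window,
      gmt_constraint_degC = cfg$constraint,
      n_boot = cfg$n_boot, percentile = cfg$percentile,
      emergence_rule = "strict exceedance (exposure > threshold)",
      threshold_rule = "nearest-rank percentile of pooled cross-run sample",
      bootstrap_rule = "years iid with replacement, shared across cells per country",
      tie_rule = "argmin ties to earliest source year",
      edge_rule = "rolling mean window shrunk symmetrically at edges"
    ),
    ensemble_membership = purrr::map(
      seq_len(nrow(result$ensemble_sizes)), function(i) {
        list(pathway = result$ensemble_sizes$pathway[i],
             n_runs = result$ensemble_sizes$n_runs[i],
             runs = unlist(result$ensemble_sizes$runs[i]))
      }),
    empty_pathways = result$empty_pathways
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}
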