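#' Build incrementally warming GMT pathways from anchor trajectories
#'
#' For each target end-of-century warming level between `lo` and `hi`
#' (step `step`), the pathway is the year-wise linear interpolation between
#' the two anchor trajectories whose 2100 levels bracket the target, with
#' weights set by the 2100 levels; a target that equals an anchor level
#' passes the anchor through unchanged. The default 1.5-3.5 degC range at
#' 0.1 degC steps yields 21 pathways.
#'
#' @param anchors Tibble with columns `anchor`, `year`, `gmt` (e.g. from
#'   [gen_gmt_anchors()]); each anchor's level is its value at year 2100.
#' @param lo,hi,step Target levels `seq(lo, hi, step)` (degrees C).
#' @return Tibble: `pathway` (numeric level), `year`, `gmt`.
#' @export
#' @examples
#' p <- build_pathways(gen_gmt_anchors(c(1.5, 3.5)))
#' length(unique(p$pathway))  # 21
build_pathways <- function(anchors, lo = 1.5, hi = 3.5, step = 0.1) {
  stop_if_missing_cols(anchors, c("anchor", "year", "gmt"), "anchors")
  levels2100 <- anchors |>
    filter(.data$year == 2100) |>
    arrange(.data$anchor)
  if (nrow(levels2100) < 2) {
    abort("build_pathways(): need at least two anchor trajectories with a year-2100 value.")
  }
  av <- levels2100$gmt
  aid <- levels2100$anchor
  targets <- round(seq(lo, hi, by = step), 6)
  if (min(targets) < min(av) - 1e-9 || max(targets) > max(av) + 1e-9) {
    abort(sprintf(
      "build_pathways(): target range [%.2f, %.2f] outside anchor 2100 span [%.2f, %.2f].",
      min(targets), max(targets), min(av), max(av)))
  }
  wide <- anchors |>
    arrange(.data$anchor, .data$year) |>
    tidyr::pivot_wider(names_from = "anchor", values_from = "gmt")
  yrs <- wide$year
  amat <- as.matrix(wide[, as.character(aid), drop = FALSE])

  purrr::map_dfr(targets, function(tg) {
    j <- which(abs(av - tg) < 1e-9)
    if (length(j) == 1) {
      g <- amat[, j]
    } else {
      hi_i <- which(av > tg)[1]
      lo_i <- hi_i - 1
      w <- (tg - av[lo_i]) / (av[hi_i] - av[lo_i])
      g <- (1 - w) * amat[, lo_i] + w * amat[, hi_i]
    }
    tibble(pathway = tg, year = yrs, gmt = g)
  })
}

#' Smooth GMT series with a centered 21-year rolling mean
#'
#' The window shrinks symmetrically near the series edges so every year
#' keeps a value. A series shorter than the window triggers a warning and is
#' replaced by its full-series mean.
#'
#' @param gmt Tibble with columns `year`, `gmt` and optionally `run` (each
#'   run smoothed separately).
#' @param window Window length in years (default 21).
#' @return The input with a `gmt_smooth` column added.
#' @export
smooth_gmt <- function(gmt, window = 21L) {
  stop_if_missing_cols(gmt, c("year", "gmt"), "GMT series")
  smooth_one <- function(d) {
    d <- arrange(d, .data$year)
    if (nrow(d) < window) {
      warn(sprintf(
        "smooth_gmt(): series of %d years is shorter than the %d-year window; using the full-series mean.",
        nrow(d), window))
      d$gmt_smooth <- mean(d$gmt)
    } else {
      d$gmt_smooth <- roll_mean_shrink(d$gmt, window)
    }
    d
  }
  if ("run" %in% names(gmt)) {
    gmt |> group_by(.data$run) |> group_modify(~ smooth_one(.x)) |> ungroup()
  } else {
    smooth_one(gmt)
  }
}

#' Map target-pathway years onto a run's analogue years by warming level
#'
#' For every target year of every pathway, the source year is the run year
#' whose smoothed GMT is closest to the pathway's GMT (ties broken toward
#' the earliest source year). The mapping's maximum absolute warming
#' discrepancy is recorded and the mapping is flagged invalid when it
#' exceeds `constraint` (default 0.2 degC) — invalid mappings are flagged,
#' never raised.
#'
#' @param gmt_smooth Tibble with columns `run`, `year`, `gmt_smooth` (from
#'   [smooth_gmt()]).
#' @param pathways Pathway tibble from [build_pathways()].
#' @param constraint Maximum tolerated warming discrepancy (degC).
#' @param target_years Target years of the mapping (default 1960-2113).
#' @return Tibble: `run`, `pathway`, `year` (target), `source_year`,
#'   `discrepancy`, `max_discrepancy`, `valid`.
#' @export
map_years <- function(gmt_smooth, pathways, constraint = 0.2,
                      target_years = 1960:2113) {
  stop_if_missing_cols(gmt_smooth, c("run", "year", "gmt_smooth"),
                       "smoothed GMT")
  stop_if_missing_cols(pathways, c("pathway", "year", "gmt"), "pathways")
  runs <- unique(gmt_smooth$run)
  pws <- unique(pathways$pathway)
  purrr::map_dfr(runs, function(rn) {
    g <- gmt_smooth |> filter(.data$run == rn) |> arrange(.data$year)
    purrr::map_dfr(pws, function(pw) {
      p <- pathways |>
        filter(.data$pathway == pw, .data$year %in% target_years) |>
        arrange(.data$year)
      d <- abs(outer(g$gmt_smooth, p$gmt, "-"))
      # earliest source year among (near-)ties; the 1e-9 degC tolerance makes
      # the tie rule robust to floating-point asymmetry
      idx <- apply(d, 2, function(col) which(col <= min(col) + 1e-9)[1])
      disc <- d[cbind(idx, seq_along(idx))]
      D <- max(disc)
      tibble(run = rn, pathway = pw, year = p$year,
             source_year = g$year[idx], discrepancy = disc,
             max_discrepancy = D, valid = D <= constraint + 1e-12)
    })
  })
}

#' Resample an exposure field onto pathway years
#'
#' Output year `t` carries the field of the mapping's source year `s(t)`;
#' provenance (pathway id, source year) travels with every row. Invalid
#' mappings are refused with their discrepancy in the message.
#'
#' @param field Exposure tibble with columns `run`, `year`, `cell`, `f`
#'   covering all source years of the mapping.
#' @param mapping Mapping tibble from [map_years()] (one or more
#'   run-pathway combinations).
#' @return Tibble: `run`, `pathway`, `year`, `source_year`, `cell`, `f`.
#' @export
resample_exposure <- function(field, mapping) {
  stop_if_missing_cols(field, c("run", "year", "cell", "f"), "exposure field")
  stop_if_missing_cols(mapping,
                       c("run", "pathway", "year", "source_year", "valid"),
                       "year mapping")
  bad <- mapping |> filter(!.data$valid) |>
    distinct(.data$run, .data$pathway, .data$max_discrepancy)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "resample_exposure(): mapping run %s -> pathway %.1f is invalid (max warming discrepancy %.3f degC > constraint).",
      bad$run[1], bad$pathway[1], bad$max_discrepancy[1]))
  }
  miss <- mapping |>
    anti_join(distinct(field, .data$run, .data$year),
              by = c("run", source_year = "year"))
  if (nrow(miss) > 0) {
    abort(sprintf(
      "resample_exposure(): field for run %s does not cover source year %d.",
      miss$run[1], miss$source_year[1]))
  }
  mapping |>
    select("run", "pathway", "year", "source_year") |>
    inner_join(field, by = c("run", source_year = "year"),
               relationship = "many-to-many") |>
    select("run", "pathway", "year", "source_year", "cell", "f")
}

#' Ensemble membership per pathway
#'
#' Number of runs whose warming-level mapping is valid for each pathway;
#' matching higher pathways needs runs that warm at least that far, so
#' membership is non-increasing in pathway level for a fixed run set.
#'
#' @param mapping Mapping tibble from [map_years()].
#' @return Tibble: `pathway`, `n_runs`, `runs` (list column).
#' @export
ensemble_sizes <- function(mapping) {
  mapping |>
    distinct(.data$run, .data$pathway, .data$valid) |>
    filter(.data$valid) |>
    group_by(.data$pathway) |>
    summarise(n_runs = n(), runs = list(sort(.data$run)), .groups = "drop") |>
    tidyr::complete(pathway = unique(mapping$pathway),
                    fill = list(n_runs = 0L)) |>
    arrange(.data$pathway)
}
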