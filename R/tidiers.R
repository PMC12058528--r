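#' Broom-style tidiers
#'
#' `tidy()` returns per-unit summaries, `glance()` one-row overviews, for
#' the package's fitted/result objects.
#'
#' @param x A `baseline_sample`, `ule_test` or `ule_result`.
#' @param percentile Threshold percentile for `tidy.baseline_sample()`.
#' @param ... Ignored.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.baseline_sample <- function(x, percentile = 99.99, ...) {
  tibble(
    cell = x$cells,
    n = ncol(x$samples),
    mean = rowMeans(x$samples),
    sd = apply(x$samples, 1, sd),
    threshold = apply(x$samples, 1, nearest_rank_percentile, p = percentile)
  )
}

#' @rdname tidiers
#' @export
glance.baseline_sample <- function(x, ...) {
  tibble(n_cells = nrow(x$samples), n_runs = length(x$runs),
         n_boot = x$n_boot, pooled_n = ncol(x$samples), seed = x$seed)
}

#' @rdname tidiers
#' @export
tidy.ule_test <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidiers
#' @export
tidy.ule_result <- function(x, ...) {
  as_tibble(x$cf_summary)
}

#' @rdname tidiers
#' @export
glance.ule_result <- function(x, ...) {
  tibble(
    n_birth_years = length(unique(x$cf$birth_year)),
    n_pathways = length(unique(x$cf$pathway)),
    n_empty_pathways = length(x$empty_pathways),
    min_ensemble = min(x$ensemble_sizes$n_runs),
    max_ensemble = max(x$ensemble_sizes$n_runs),
    cf_mean_last = {
      last_by <- max(x$cf_summary$birth_year)
      top <- dplyr::filter(x$cf_summary, .data$birth_year == last_by)
      top$cf_mean[which.max(top$pathway)]
    },
    seed = x$config$seed
  )
}
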