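#' Plot cohort-fraction ensemble statistics
#'
#' Ensemble-mean cohort fraction against birth year, one line per pathway,
#' with the interquartile ensemble range as a ribbon — the tabular
#' equivalent of a birth-year x warming-level summary figure.
#'
#' @param object A `"ule_cf_summary"` from [summarize_cohort_fraction()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ule_cf_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$birth_year, y = .data$cf_mean,
                               colour = factor(.data$pathway),
                               fill = factor(.data$pathway))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cf_q25,
                                      ymax = .data$cf_q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Birth year", y = "Cohort fraction with ULE",
                  colour = "Pathway (degC)", fill = "Pathway (degC)") +
    ggplot2::theme_minimal()
}

#' Heat-grid of cohort fraction over birth year and pathway level
#'
#' @param cf_summary A `"ule_cf_summary"`.
#' @return A ggplot object.
#' @export
plot_cf_heatgrid <- function(cf_summary) {
  ggplot2::ggplot(cf_summary,
                  ggplot2::aes(x = .data$birth_year,
                               y = factor(.data$pathway),
                               fill = .data$cf_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Birth year", y = "Pathway (degC by 2100)",
                  fill = "CF") +
    ggplot2::theme_minimal()
}

#' Pre-industrial lifetime-exposure distribution for one cell
#'
#' Histogram of the pooled bootstrap sample with the emergence threshold
#' (dashed) and, optionally, projected lifetime exposures overlaid.
#'
#' @param baseline A [bootstrap_preindustrial()] result.
#' @param cell Cell id.
#' @param percentile Threshold percentile (default 99.99).
#' @param lifetime_exposures Optional numeric vector of projected lifetime
#'   exposures to overlay.
#' @return A ggplot object.
#' @export
plot_baseline_distribution <- function(baseline, cell, percentile = 99.99,
                                       lifetime_exposures = NULL) {
  stopifnot(inherits(baseline, "baseline_sample"))
  i <- match(cell, baseline$cells)
  if (is.na(i)) abort(sprintf("cell %s not in baseline", format(cell)))
  s <- baseline$samples[i, ]
  thr <- nearest_rank_percentile(s, percentile)
  p <- ggplot2::ggplot(tibble(exposure = s),
                       ggplot2::aes(x = .data$exposure)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "Lifetime exposure (event-years)", y = "Count",
                  subtitle = sprintf("cell %s: %.4g-th percentile = %.3g",
                                     format(cell), percentile, thr)) +
    ggplot2::theme_minimal()
  if (!is.null(lifetime_exposures)) {
    p <- p + ggplot2::geom_vline(xintercept = lifetime_exposures,
                                 colour = "firebrick")
  }
  p
}

#' Plot strata comparison
#'
#' Ensemble-mean emerged fraction per vulnerability stratum and birth year
#' with +-1 SD error bars across ensemble members.
#'
#' @param strata A [strata_ule()] result.
#' @return A ggplot object.
#' @export
plot_strata <- function(strata) {
  ggplot2::ggplot(strata,
                  ggplot2::aes(x = factor(.data$birth_year),
                               y = .data$fraction_mean,
                               fill = factor(.data$stratum))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fraction_mean - .data$fraction_sd,
                   ymax = .data$fraction_mean + .data$fraction_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = "Birth year", y = "Fraction with ULE",
                  fill = "Stratum") +
    ggplot2::theme_minimal()
}
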