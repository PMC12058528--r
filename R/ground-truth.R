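# Exact distribution machinery for synthetic-world ground truth.
#
# Under the synthetic occurrence model a lifetime exposure is
#   E = a * ( sum_s w_s X_s )          X_s ~ Bernoulli(p_s) independent,
# where s runs over *distinct* source years of the lifetime and w_s counts
# how often the warming-level mapping reuses that source year (plus the
# fractional weight of the final lived year). With integer w the sum lives
# on a lattice, so tail probabilities are exact by convolution; the single
# fractionally weighted source is handled by conditioning on its indicator.

# pmf of sum(w_i X_i) for integer weights w, X_i ~ Bern(p_i); support 0..sum(w)
int_weighted_pmf <- function(w, p) {
  pmf <- rep(0, sum(w) + 1)
  pmf[1] <- 1
  for (i in seq_along(w)) {
    shifted <- c(rep(0, w[i]), pmf[seq_len(length(pmf) - w[i])])
    pmf <- pmf * (1 - p[i]) + shifted * p[i]
  }
  pmf
}

# P(a * (sum w_i X_i + w_f X_f) > threshold), w integer, w_f real or NULL
weighted_exceed_prob <- function(threshold, p, w, a = 1,
                                 p_final = NULL, w_final = 0) {
  keep <- w > 0
  pmf <- if (any(keep)) int_weighted_pmf(w[keep], p[keep]) else 1
  s <- (seq_along(pmf) - 1) * a
  if (is.null(p_final) || w_final <= 0) return(sum(pmf[s > threshold]))
  (1 - p_final) * sum(pmf[s > threshold]) +
    p_final * sum(pmf[s + a * w_final > threshold])
}

# Distinct-source weights of a lifetime: integer multiplicities of each
# source year over the fully lived years, plus the fractional weight of the
# final year's source (kept separate for exact conditioning).
lifetime_source_weights <- function(source_years, L) {
  fl <- floor(L)
  frac <- L - fl
  full <- source_years[seq_len(min(fl, length(source_years)))]
  tab <- table(full)
  out <- list(source = as.integer(names(tab)), w = as.integer(tab),
              final_source = NA_integer_, frac = 0)
  if (frac > 1e-12 && length(source_years) >= fl + 1) {
    out$final_source <- source_years[fl + 1]
    out$frac <- frac
  }
  out
}

#' Exact stationary lifetime-exposure quantile and false-emergence rate
#'
#' Under a stationary pre-industrial climate with annual occurrence
#' probability `p0` and exposed fraction `a`, a lifetime exposure is
#' `a * (Binomial(floor(L), p0) + frac * Bernoulli(p0))`. These helpers give
#' the exact distribution's smallest support value with CDF at least
#' `percentile / 100` (the true emergence threshold) and the exact
#' probability of strictly exceeding an arbitrary threshold (the
#' false-emergence rate of the one-in-ten-thousand rule).
#'
#' @param p0 Annual occurrence probability.
#' @param a Exposed fraction given occurrence.
#' @param L Life expectancy in years (may be fractional).
#' @param percentile Percentile of the stationary distribution (default
#'   99.99).
#' @param threshold Emergence threshold (event-years).
#' @return `true_ule_quantile()`: the exact quantile (event-years);
#'   `stationary_false_emergence()`: the exact exceedance probability.
#' @export
#' @examples
#' true_ule_quantile(0.01, 1, 60)   # 5 events
#' stationary_false_emergence(0.01, 1, 60, 5)
true_ule_quantile <- function(p0, a, L, percentile = 99.99) {
  d <- stationary_lifetime_dist(p0, a, L)
  d$value[which(cumsum(d$prob) >= percentile / 100 - 1e-12)[1]]
}

#' @rdname true_ule_quantile
#' @export
stationary_false_emergence <- function(p0, a, L, threshold) {
  d <- stationary_lifetime_dist(p0, a, L)
  sum(d$prob[d$value > threshold])
}

stationary_lifetime_dist <- function(p0, a, L) {
  fl <- floor(L)
  frac <- L - fl
  pmf <- int_weighted_pmf(rep(1L, fl), rep(p0, fl))
  v <- (seq_along(pmf) - 1) * a
  if (frac > 1e-12) {
    value <- c(v, v + frac * a)
    prob <- c(pmf * (1 - p0), pmf * p0)
  } else {
    value <- v
    prob <- pmf
  }
  o <- order(value)
  agg <- rowsum(prob[o], group = value[o])
  tibble(value = as.numeric(rownames(agg)), prob = as.numeric(agg))
}

#' Analytic ground-truth cohort fraction for a synthetic world
#'
#' Computes, exactly, the expected cohort fraction reaching unprecedented
#' lifetime exposure in a synthetic world, conditional on the realized
#' per-cell emergence thresholds and the realized warming-level year
#' mappings. The only randomness left in a measured cohort fraction is then
#' the Bernoulli occurrence draws, whose exact per-run variance is also
#' returned, so measured ensemble-mean CF can be compared to `cf_true`
#' within Monte-Carlo standard deviations.
#'
#' @param ens An [gen_exposure_ensemble()] result.
#' @param mapping Year mapping tibble from [map_years()] (all runs and
#'   pathways; invalid mappings are skipped).
#' @param thresholds Tibble `cell`, `threshold` (e.g. from
#'   [ule_threshold()], or true quantiles).
#' @param cohort_sizes Tibble `cell`, `birth_year`, `cohort_size`.
#' @param le_annual Tibble `country`, `birth_year`, `le`.
#' @param birth_years Birth years to evaluate.
#' @return Tibble: `pathway`, `birth_year`, `cf_true`, `cf_sd` (standard
#'   deviation of the measured ensemble-mean CF), `n_runs`.
#' @export
true_cohort_fraction <- function(ens, mapping, thresholds, cohort_sizes,
                                 le_annual, birth_years) {
  stopifnot(inherits(ens, "exposure_ensemble"))
  grid <- ens$grid
  params <- ens$params
  ws_by_run <- ens$gmt |>
    group_by(.data$run) |>
    summarise(year = list(.data$year),
              ws = list(roll_mean_shrink(.data$gmt, 21L)), .groups = "drop")

  map_valid <- mapping |> filter(.data$valid)
  combos <- map_valid |> distinct(.data$run, .data$pathway)
  if (nrow(combos) == 0) abort("true_cohort_fraction(): no valid mappings.")

  cell_info <- grid |>
    filter(!is.na(.data$country)) |>
    left_join(params, by = "cell") |>
    left_join(thresholds, by = "cell")

  out <- list()
  for (i in seq_len(nrow(combos))) {
    rn <- combos$run[i]; pw <- combos$pathway[i]
    mp <- map_valid |> filter(.data$run == rn, .data$pathway == pw)
    src <- mp$source_year[order(mp$year)]
    tgt <- sort(mp$year)
    wrow <- ws_by_run[ws_by_run$run == rn, ]
    ws <- wrow$ws[[1]]
    wyears <- wrow$year[[1]]

    for (b in birth_years) {
      res_b <- purrr::map_dfr(unique(cell_info$country), function(cc) {
        L <- le_annual$le[le_annual$country == cc & le_annual$birth_year == b]
        if (length(L) != 1) {
          abort(sprintf("true_cohort_fraction(): no life expectancy for country %s, birth year %d.", cc, b))
        }
        life_t <- b:(b + ceiling(L) - 1)
        idx <- match(life_t, tgt)
        if (anyNA(idx)) {
          abort("true_cohort_fraction(): lifetime extends beyond mapped target years.")
        }
        sw <- lifetime_source_weights(src[idx], L)
        p_of <- function(p0x, betax, syrs) {
          clamp01(p0x + betax * ws[match(syrs, wyears)])
        }
        cells <- cell_info |> filter(.data$country == cc)
        # cells sharing (p0, beta, a, threshold) have identical exceedance
        groups <- cells |>
          distinct(.data$p0, .data$beta, .data$a, .data$threshold) |>
          mutate(pe = purrr::pmap_dbl(
            list(.data$p0, .data$beta, .data$a, .data$threshold),
            function(p0x, betax, ax, Tx) {
              pf <- if (!is.na(sw$final_source))
                p_of(p0x, betax, sw$final_source) else NULL
              weighted_exceed_prob(Tx, p_of(p0x, betax, sw$source), sw$w,
                                   a = ax, p_final = pf, w_final = sw$frac)
            }))
        cells |>
          left_join(groups, by = c("p0", "beta", "a", "threshold")) |>
          select("cell", "pe")
      })
      bb <- cohort_sizes |> filter(.data$birth_year == b) |>
        inner_join(res_b, by = "cell")
      tot <- sum(bb$cohort_size)
      out[[length(out) + 1]] <- tibble(
        run = rn, pathway = pw, birth_year = b,
        cf_true = sum(bb$cohort_size * bb$pe) / tot,
        var_run = sum(bb$cohort_size^2 * bb$pe * (1 - bb$pe)) / tot^2
      )
    }
  }
  bind_rows(out) |>
    group_by(.data$pathway, .data$birth_year) |>
    summarise(cf_true = mean(.data$cf_true),
              cf_sd = sqrt(sum(.data$var_run)) / n(),
              n_runs = n(), .groups = "drop")
}
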