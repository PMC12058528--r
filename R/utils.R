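#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join semi_join anti_join bind_rows distinct pull n
#'   rename across count slice group_modify
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats quantile rbinom rnorm runif approx median t.test
#'   wilcox.test qnorm sd var cor
#' @importFrom utils head tail
NULL

clamp01 <- function(x) pmax(pmin(x, 1), 0)  # argument order keeps dim attributes

#' Derive a reproducible child seed from a master seed and a tag
#'
#' Deterministic hashing of a character tag onto a 31-bit integer offset so
#' that every stage and stream of the pipeline gets its own RNG seed that
#' depends only on the master seed and the stream name, never on execution
#' order.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric tags identifying the stream (stage name,
#'   run id, country id, ...). Concatenated with "/".
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "bootstrap", "run1")
derive_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- 0
  m <- 2^31 - 1
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% m
  as.integer((as.numeric(master) %% m + h) %% m)
}

# Centered rolling mean with the window shrunk symmetrically at the edges:
# at position i the half-window is min(h, i - 1, n - i) so early and late
# years are averaged over the years actually available.
roll_mean_shrink <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    mean(x[(i - hh):(i + hh)])
  }, numeric(1))
}

#' Nearest-rank empirical percentile
#'
#' The sample value at rank `ceiling((p / 100) * n)` of the sorted sample —
#' the empirical quantile convention used for the pre-industrial emergence
#' threshold, guaranteeing the returned value is an element of the sample.
#'
#' @param x Numeric sample (non-empty).
#' @param p Percentile in (0, 100].
#' @return A single sample element.
#' @export
#' @examples
#' nearest_rank_percentile(1:100, 99.99)
nearest_rank_percentile <- function(x, p) {
  if (length(x) == 0) abort("nearest_rank_percentile(): empty sample.")
  if (p <= 0 || p > 100) abort("nearest_rank_percentile(): p must be in (0, 100].")
  r <- min(length(x), max(1L, ceiling(p / 100 * length(x))))
  sort(x, partial = r)[r]
}

# Poisson-binomial pmf of the number of successes among independent
# Bernoulli(p_i), by direct convolution. Lengths here are lifetimes
# (<= ~110 terms) so O(n^2) is exact and cheap.
poisbinom_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

# P(S > k) for S ~ PoissonBinomial(p); k may be fractional (strict
# exceedance of a non-integer threshold).
poisbinom_sf <- function(k, p) {
  pmf <- poisbinom_pmf(p)
  s <- seq_along(pmf) - 1
  sum(pmf[s > k])
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
}
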