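# Small fixture builders shared across test files. Everything is generated
# in code; seeds are fixed so expected values frozen in the tests stay valid.

two_run_set <- function(scenarios = c("rcp26", "rcp85")) {
  tibble::tibble(
    run = paste0("r", seq_along(scenarios)),
    gcm = paste0("g", seq_along(scenarios)),
    impact_model = "m1",
    scenario = scenarios
  )
}

# a toy exposure field: one run, given years, cells 1..n_cell, constant f
constant_field <- function(years, n_cell = 1, f = 1, run = "r1") {
  tidyr::expand_grid(run = run, year = years, cell = seq_len(n_cell)) |>
    dplyr::mutate(f = f)
}

# full 13-block life-expectancy table for one or more countries
le_block_table <- function(countries = 1, le = 60) {
  tidyr::expand_grid(country = countries,
                     block_start = seq(1950, 2015, 5)) |>
    dplyr::mutate(block_end = block_start + 5, le = le)
}

# cohort table covering 1950-2100 x all age groups with constant group size
cohort_table <- function(countries = 1, size = 5e6) {
  ages <- c(paste(seq(0, 95, 5), seq(4, 99, 5), sep = "-"), "100+")
  tidyr::expand_grid(country = countries, year = seq(1950, 2100, 5),
                     age_group = ages) |>
    dplyr::mutate(size = size)
}

# naive reference implementation of cumulative lifetime exposure: an
# explicit year loop per cell, independent of the package's join-based path
naive_lifetime_exposure <- function(field, birth_year, L) {
  fl <- floor(L)
  frac <- L - fl
  cells <- sort(unique(field$cell))
  vapply(cells, function(x) {
    tot <- 0
    for (k in 0:(fl - 1)) {
      tot <- tot + field$f[field$cell == x & field$year == birth_year + k]
    }
    if (frac > 0) {
      tot <- tot + frac * field$f[field$cell == x &
                                    field$year == birth_year + fl]
    }
    tot
  }, numeric(1))
}
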