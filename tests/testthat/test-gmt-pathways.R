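test_that("pathway construction interpolates between bracketing anchors", {
  anch <- gen_gmt_anchors(c(1.5, 3.5))
  pw <- build_pathways(anch, lo = 1.5, hi = 3.5, step = 0.1)
  expect_equal(length(unique(pw$pathway)), 21)

  # a target halfway between two anchors is their year-wise average
  mid <- pw |> dplyr::filter(pathway == 2.5) |> dplyr::arrange(year)
  a15 <- anch |> dplyr::filter(anchor == 1.5) |> dplyr::arrange(year)
  a35 <- anch |> dplyr::filter(anchor == 3.5) |> dplyr::arrange(year)
  expect_equal(mid$gmt, (a15$gmt + a35$gmt) / 2)

  # a target equal to an anchor level passes through unchanged
  at15 <- pw |> dplyr::filter(pathway == 1.5) |> dplyr::arrange(year)
  expect_equal(at15$gmt, a15$gmt)

  expect_error(build_pathways(anch, lo = 1.0, hi = 3.5), "outside anchor")
  expect_error(build_pathways(anch, lo = 1.5, hi = 4.0), "outside anchor")
})

test_that("21-year smoothing is exact on constants and linear trends", {
  const <- tibble::tibble(year = 1901:2000, gmt = 0.7)
  expect_equal(smooth_gmt(const)$gmt_smooth, rep(0.7, 100))

  lin <- tibble::tibble(year = 1901:2000, gmt = 0.01 * (1901:2000 - 1900))
  sm <- smooth_gmt(lin)
  # symmetric window on a linear trend returns the trend (everywhere, since
  # the edge rule shrinks the window symmetrically)
  expect_equal(sm$gmt_smooth, lin$gmt, tolerance = 1e-12)

  # step 0 -> 1 at year y: smoothed value at y averages 10 zeros and 11
  # ones, 11/21
  step <- tibble::tibble(year = 1901:2000,
                         gmt = as.numeric(1901:2000 >= 1950))
  sms <- smooth_gmt(step)
  expect_equal(sms$gmt_smooth[sms$year == 1950], 11 / 21)

  short <- tibble::tibble(year = 2001:2010, gmt = 1:10)
  expect_warning(out <- smooth_gmt(short), "shorter")
  expect_true(all(out$gmt_smooth == 5.5))
})

test_that("warming-level matching picks the closest year, earliest on ties", {
  # W(s) = 1.0 + 0.01 (s - 2000); target 1.155 is equidistant from 2015 and
  # 2016 -> earliest source year 2015
  gs <- tibble::tibble(run = "r1", year = 1990:2030,
                       gmt_smooth = 1 + 0.01 * (1990:2030 - 2000))
  pw <- tibble::tibble(pathway = 2, year = 2000, gmt = 1.155)
  mp <- map_years(gs, pw, target_years = 2000)
  expect_equal(mp$source_year, 2015)
  expect_equal(mp$discrepancy, 0.005, tolerance = 1e-12)

  # a run mapped onto its own trajectory is the identity with D = 0
  pw_self <- tibble::tibble(pathway = 9, year = 1990:2030,
                            gmt = gs$gmt_smooth)
  mp_self <- map_years(gs, pw_self, target_years = 1990:2030)
  expect_equal(mp_self$source_year, mp_self$year)
  expect_equal(max(mp_self$discrepancy), 0)
  expect_true(all(mp_self$valid))

  # a run whose maximum warming falls 0.3 degC short is flagged invalid
  pw_hot <- tibble::tibble(pathway = 8, year = 2000, gmt = max(gs$gmt_smooth) + 0.3)
  mp_hot <- map_years(gs, pw_hot, target_years = 2000)
  expect_false(any(mp_hot$valid))
  expect_gte(max(mp_hot$max_discrepancy), 0.3)
})

test_that("resampling relabels years bit-identically and refuses invalid maps", {
  set.seed(1)
  field <- tidyr::expand_grid(run = "r1", year = 2001:2003, cell = 1:4) |>
    dplyr::mutate(f = round(runif(dplyr::n()), 6))
  # toy mapping [A,B,C] -> [B,B,C]
  mp <- tibble::tibble(run = "r1", pathway = 1.5, year = 2001:2003,
                       source_year = c(2002, 2002, 2003),
                       discrepancy = 0, max_discrepancy = 0, valid = TRUE)
  out <- resample_exposure(field, mp)
  b <- field |> dplyr::filter(year == 2002) |> dplyr::arrange(cell)
  expect_equal(out$f[out$year == 2001][order(out$cell[out$year == 2001])],
               b$f)
  expect_equal(out$f[out$year == 2002][order(out$cell[out$year == 2002])],
               b$f)
  # value-set preservation: every output year equals some source year's field
  for (y in unique(out$year)) {
    fy <- out |> dplyr::filter(year == y) |> dplyr::arrange(cell)
    match_any <- any(vapply(unique(field$year), function(s) {
      fs <- field |> dplyr::filter(year == s) |> dplyr::arrange(cell)
      identical(fs$f, fy$f)
    }, logical(1)))
    expect_true(match_any)
  }

  mp_bad <- mp |> dplyr::mutate(valid = FALSE, max_discrepancy = 0.31)
  expect_error(resample_exposure(field, mp_bad), "0.310")
  mp_miss <- mp |> dplyr::mutate(source_year = c(1999, 2002, 2003))
  expect_error(resample_exposure(field, mp_miss), "source year 1999")
})

test_that("ensemble size is non-increasing in pathway level", {
  cfg <- synth_config(n_lat = 2, n_lon = 2, n_countries = 1,
                      runs = two_run_set(c("rcp26", "rcp60", "rcp85")),
                      seed = 6)
  ens <- gen_exposure_ensemble(cfg)
  pw <- build_pathways(gen_gmt_anchors(cfg))
  gs <- smooth_gmt(dplyr::select(ens$gmt, run, year, gmt))
  sizes <- ensemble_sizes(map_years(gs, pw))
  sizes <- sizes |> dplyr::arrange(pathway)
  expect_true(all(diff(sizes$n_runs) <= 0))
  expect_gt(sizes$n_runs[1], sizes$n_runs[nrow(sizes)])  # staggered run set
})
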