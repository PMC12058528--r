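#' Write / read gridded annual fields as self-describing CSV
#'
#' Long-format CSV (one row per cell-year) accompanied by a JSON sidecar
#' (`<path>.json`) recording the dimensions, coordinate ranges, units and
#' any metadata, so the file round-trips without outside knowledge.
#'
#' @param field Tibble with at least `cell`, `year`, and one value column.
#' @param path Output CSV path.
#' @param meta Named list of metadata stored in the sidecar.
#' @return `write_field_csv()`: the path, invisibly. `read_field_csv()`:
#'   the tibble, with the sidecar (if present) attached as attribute
#'   `"meta"`.
#' @export
write_field_csv <- function(field, path, meta = list()) {
  stop_if_missing_cols(field, c("cell", "year"), "field")
  readr::write_csv(field, path)
  side <- c(list(
    columns = names(field),
    n_cells = length(unique(field$cell)),
    years = range(field$year)
  ), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stop_if_missing_cols(out, c("cell", "year"), basename(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) attr(out, "meta") <- jsonlite::read_json(side)
  out
}

#' Validating readers for demographic tables
#'
#' CSV readers for the 5-year life-expectancy blocks and 5-year cohort-size
#' tables; both check required columns and report row-level failures.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_le_blocks <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stop_if_missing_cols(d, c("country", "block_start", "le"), basename(path))
  bad <- which(!is.finite(d$le) | d$le <= 0)
  if (length(bad) > 0) {
    abort(sprintf("read_le_blocks(): non-positive life expectancy at row %d.",
                  bad[1]))
  }
  d
}

#' @rdname read_le_blocks
#' @export
read_cohort_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stop_if_missing_cols(d, c("country", "year", "age_group", "size"),
                       basename(path))
  bad <- which(!is.finite(d$size) | d$size < 0)
  if (length(bad) > 0) {
    abort(sprintf("read_cohort_table(): invalid size at row %d.", bad[1]))
  }
  d
}
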