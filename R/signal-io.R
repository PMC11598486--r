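# Delimited-text interchange for sampled multi-axis series. Comma-separated,
# "." decimal, one header row; an optional `time` (or `t`) column plus one
# numeric column per axis.

#' Read a multi-axis time series from a delimited text file
#'
#' @param path Path to a CSV file with a header row.
#' @param columns Names of the axis columns to read; `NULL` reads every
#'   column except a `time`/`t` column.
#' @param dt Sampling interval in seconds, used to build a `time` column
#'   when the file has none. Defaults to 1.
#' @return A wide tibble with `time` plus one numeric column per axis and
#'   attribute `dt`; all rows in file order.
#' @seealso [write_series()]
#' @export
read_series <- function(path, columns = NULL, dt = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("empty series: %s has a header but no data rows", path))
  time_col <- intersect(c("time", "t"), names(raw))[1]
  if (is.null(columns)) {
    columns <- setdiff(names(raw), c("time", "t"))
  }
  missing <- setdiff(columns, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Column(s) not found in %s: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (length(columns) == 0) abort("No axis columns to read.")
  parse_col <- function(nm) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column `%s` at row %d: \"%s\"",
                    nm, bad[1], raw[[nm]][bad[1]]))
    }
    v
  }
  out <- purrr::map(columns, parse_col) |> setNames(columns) |> as_tibble()
  if (!is.na(time_col) && !is.null(time_col)) {
    tv <- parse_col(time_col)
    out <- dplyr::bind_cols(tibble(time = tv), out)
    if (is.null(dt) && length(tv) > 1) dt <- tv[2] - tv[1]
  } else {
    if (is.null(dt)) dt <- 1
    out <- dplyr::bind_cols(tibble(time = (seq_len(nrow(out)) - 1) * dt), out)
  }
  if (nrow(out) < 2) abort("A series needs at least 2 samples.")
  attr(out, "dt") <- dt
  out
}

#' Write a multi-axis time series to a delimited text file
#'
#' Writes a CSV readable by [read_series()]; numeric values are written at
#' full double precision so a write/read round trip preserves values.
#'
#' @param signal A wide tibble with a `time` column and one numeric column
#'   per axis.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(signal, path) {
  stopifnot(is.data.frame(signal))
  axes <- setdiff(names(signal), c("time", "t"))
  if (length(axes) == 0) abort("`signal` has no axis columns to write.")
  for (nm in names(signal)) check_numeric_vector(signal[[nm]], nm, min_len = 1)
  readr::write_csv(as_tibble(signal), path, progress = FALSE)
  invisible(path)
}
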