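strict_numeric <- function(chr, col, path, call = rlang::caller_env()) {
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(out) & !(is.na(chr) | chr == "" | toupper(chr) == "NA"))
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-numeric value %s in column `%s` of %s (data row %s).",
      dQuote(chr[bad[1]]), col, path,
      paste(utils::head(bad, 5), collapse = ", ")), call = call)
  }
  out
}

#' Read a paired series from a delimited text file
#'
#' Reads two numeric columns as a paired series. Columns are selected by name
#' (`x_col` / `y_col`) when a header is present, otherwise the first two
#' columns are used. Parsing is strict: any non-numeric cell aborts with its
#' row number, and missing values are rejected (dropping rows would silently
#' destroy the serial structure the tests rely on).
#'
#' @param path File path.
#' @param x_col,y_col Column names (header required) or `NULL` for the first
#'   two columns.
#' @param delim Field delimiter (default `","`).
#' @param header Does the file have a header row? Default `TRUE`.
#' @return A tibble with columns `x` and `y`.
#' @export
read_paired_series <- function(path, x_col = NULL, y_col = NULL, delim = ",",
                               header = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- read.csv(path, sep = delim, header = header,
                  colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (ncol(raw) < 2) abort(sprintf("%s has fewer than two columns.", path))
  pick <- function(col, default_idx, what) {
    if (is.null(col)) return(raw[[default_idx]])
    if (!header) abort(sprintf("Column `%s` requested but the file has no header.", col))
    if (!col %in% names(raw)) {
      abort(sprintf("Column `%s` not found in %s (have: %s).", col, path,
                    paste(names(raw), collapse = ", ")))
    }
    raw[[col]]
  }
  x <- strict_numeric(pick(x_col, 1L), x_col %||% names(raw)[1] %||% "1", path)
  y <- strict_numeric(pick(y_col, 2L), y_col %||% names(raw)[2] %||% "2", path)
  d <- tibble::tibble(x = x, y = y)
  check_series(d$x, "x"); check_series(d$y, "y")
  d
}

#' Read a tidy station table from a CSV file
#'
#' Expects columns `station_id`, `year`, `a`, `b` (one row per station-year),
#' the input layout of [batch_station_test()]. Numeric parsing is strict with
#' row-numbered errors.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble with columns `station_id`, `year`, `a`, `b`.
#' @export
read_station_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- read.csv(path, sep = delim, header = TRUE, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  req <- c("station_id", "year", "a", "b")
  if (!all(req %in% names(raw))) {
    abort(sprintf("%s must have columns %s.", path, paste(req, collapse = ", ")))
  }
  tibble::tibble(
    station_id = raw$station_id,
    year = as.integer(strict_numeric(raw$year, "year", path)),
    a = strict_numeric(raw$a, "a", path),
    b = strict_numeric(raw$b, "b", path)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
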