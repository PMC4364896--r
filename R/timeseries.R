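#' @useDynLib pulsepop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor fitted lm median optim qlogis plogis quantile
#'   rnorm runif sd setNames Box.test ks.test predict resid
#' @importFrom utils read.csv write.csv
NULL

# Quarter labels and their fractional-year offsets. The annual cycle starts
# in February (the seedfall quarter), so internal time is year + offset with
# Feb = 0.
QUARTERS <- c(Feb = 0, May = 0.25, Aug = 0.5, Nov = 0.75)

#' Construct an annual series
#'
#' A year-indexed scalar series used for mean summer temperature (degrees C)
#' or annual seedfall (seeds per square metre). Years must be consecutive
#' integers: the seedfall driver of the consumer model cannot have holes.
#'
#' @param years Integer vector of consecutive calendar years.
#' @param values Numeric vector, one value per year.
#' @param units Free-text unit label (informational).
#' @return A data frame of class `annual_series` with columns `year`, `value`.
#' @export
annual_series <- function(years, values, units = "") {
  years <- as.integer(years)
  if (length(years) != length(values)) {
    stop("`years` and `values` must have equal length", call. = FALSE)
  }
  if (anyNA(years) || anyNA(values)) {
    stop("annual series must not contain missing values", call. = FALSE)
  }
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("non-consecutive years in annual series", call. = FALSE)
  }
  out <- data.frame(year = years, value = as.numeric(values))
  attr(out, "units") <- units
  class(out) <- c("annual_series", "data.frame")
  out
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %d years (%d-%d)%s\n", nrow(x),
              min(x$year), max(x$year),
              if (nzchar(attr(x, "units") %||% "")) paste0(" [", attr(x, "units"), "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a quarterly abundance series
#'
#' A consumer-abundance index (captures per 100 trap-nights, C/100TN) recorded
#' at the start of each quarter of a February-start year. Quarters map to
#' fractional-year offsets Feb = 0, May = 0.25, Aug = 0.5, Nov = 0.75.
#' Missing quarters are allowed (fitting skips them); duplicates are not.
#'
#' @param years Integer vector of annual-cycle years.
#' @param quarters Character vector with entries in `Feb`, `May`, `Aug`, `Nov`.
#' @param values Non-negative abundance index values.
#' @return A data frame of class `quarterly_series` with columns `year`,
#'   `quarter`, `value` and a derived fractional-year `time` column, sorted
#'   by time.
#' @export
quarterly_series <- function(years, quarters, values) {
  years <- as.integer(years)
  quarters <- as.character(quarters)
  if (length(unique(c(length(years), length(quarters), length(values)))) != 1L) {
    stop("`years`, `quarters` and `values` must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(quarters), names(QUARTERS))
  if (length(bad)) {
    stop("unknown quarter label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) {
    stop("abundance values must be non-negative and non-missing", call. = FALSE)
  }
  time <- years + unname(QUARTERS[quarters])
  if (anyDuplicated(time)) {
    stop("duplicate (year, quarter) record", call. = FALSE)
  }
  ord <- order(time)
  out <- data.frame(year = years[ord], quarter = quarters[ord],
                    value = values[ord], time = time[ord])
  class(out) <- c("quarterly_series", "data.frame")
  out
}

#' @export
print.quarterly_series <- function(x, ...) {
  cat(sprintf("<quarterly_series> %d records, %d-%d (C/100TN)\n",
              nrow(x), min(x$year), max(x$year)))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Read an annual series from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and two columns:
#' year and value. Years must be consecutive.
#'
#' @param path Path to the CSV file.
#' @param columns Length-2 character vector naming the (year, value) columns;
#'   by default the first two columns are used whatever their names.
#' @param units Unit label attached to the result.
#' @return An [annual_series].
#' @export
read_annual <- function(path, columns = NULL, units = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(columns)) {
    if (ncol(df) < 2) stop("annual CSV needs two columns (year, value)", call. = FALSE)
    columns <- names(df)[1:2]
  }
  miss <- setdiff(columns, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  yr <- df[[columns[1]]]
  va <- suppressWarnings(as.numeric(df[[columns[2]]]))
  if (anyNA(va)) stop("non-numeric value cell in ", path, call. = FALSE)
  if (anyNA(suppressWarnings(as.integer(yr)))) stop("non-numeric year cell in ", path, call. = FALSE)
  if (anyDuplicated(yr)) stop("duplicate years in ", path, call. = FALSE)
  if (length(yr) > 1 && any(diff(as.integer(yr)) != 1L)) {
    stop("non-consecutive years in ", path, call. = FALSE)
  }
  annual_series(yr, va, units = units)
}

#' Write an annual series to CSV
#'
#' @param x An [annual_series].
#' @param path Output path.
#' @param value_name Header used for the value column.
#' @return `path`, invisibly.
#' @export
write_annual <- function(x, path, value_name = "value") {
  stopifnot(inherits(x, "annual_series"))
  df <- data.frame(year = x$year, value = x$value)
  names(df)[2] <- value_name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a quarterly abundance series from CSV
#'
#' Expects header columns `year,quarter,value` with quarter labels in
#' `Feb`, `May`, `Aug`, `Nov`.
#'
#' @param path Path to the CSV file.
#' @return A [quarterly_series], sorted by (year, quarter offset).
#' @export
read_quarterly <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "quarter", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  quarterly_series(df$year, df$quarter, df$value)
}

#' Write a quarterly abundance series to CSV
#'
#' @param x A [quarterly_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quarterly <- function(x, path) {
  stopifnot(inherits(x, "quarterly_series"))
  write.csv(data.frame(year = x$year, quarter = x$quarter, value = x$value),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Temperature change between the two preceding summers
#'
#' Computes the mast-model predictor `dT_y = T_{y-1} - T_{y-2}`, indexed by
#' the seedfall year `y` it predicts. The first two years of the record have
#' no predictor and are dropped.
#'
#' @param temps An [annual_series] of mean summer temperatures (degrees C).
#' @return An [annual_series] of temperature differences, two years shorter
#'   than the input.
#' @export
compute_delta_t <- function(temps) {
  stopifnot(inherits(temps, "annual_series"))
  n <- nrow(temps)
  if (n < 3) stop("temperature series too short for delta-T (need >= 3 years)", call. = FALSE)
  y <- temps$year[3:n]
  dt <- temps$value[2:(n - 1)] - temps$value[1:(n - 2)]
  annual_series(y, dt, units = "degC")
}

#' Validate a series file and report invariant violations
#'
#' Convenience checker used by the analysis drivers: attempts to parse a CSV
#' as an annual or quarterly series and returns the violations found.
#'
#' @param path Path to a CSV file.
#' @param type `"annual"` or `"quarterly"`.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_series_file <- function(path, type = c("annual", "quarterly")) {
  type <- match.arg(type)
  res <- tryCatch({
    if (type == "annual") read_annual(path) else read_quarterly(path)
    character(0)
  }, error = function(e) conditionMessage(e))
  res
}
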