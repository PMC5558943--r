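#' Weekly search-volume series
#'
#' Container for a weekly normalized search-volume series as exported by
#' Google-Trends-style tools: one value per week start date, values on the
#' 0-100 normalized scale, with an explicit missingness mask. Missing entries
#' carry \code{NA} in \code{values} and \code{TRUE} in \code{missing}; the
#' mask is kept explicit because a displayed 0 can mean either a true low
#' volume or "insufficient data".
#'
#' @param dates vector of week start dates (\code{Date}), strictly increasing
#'   with constant 7-day spacing. Weeks are taken to start on the date given
#'   (Google Trends exports use Sunday starts).
#' @param values numeric vector of normalized volumes in [0, 100]; \code{NA}
#'   where missing.
#' @param missing optional logical mask; defaults to \code{is.na(values)}.
#' @param label search-term label.
#' @param region region code (e.g. "US", "DE", "AT", "CH").
#' @return An object of class \code{weekly_series}.
#' @export
weekly_series <- function(dates, values, missing = NULL, label = "", region = "") {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("dates and values must have the same length")
  if (length(dates) == 0L)
    stop("empty series")
  if (length(dates) > 1L) {
    dd <- diff(as.integer(dates))
    if (any(dd != 7L))
      stop("dates must be strictly increasing with constant 7-day spacing")
  }
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.logical(missing)
  if (length(missing) != length(values))
    stop("missing mask length mismatch")
  values[missing] <- NA_real_
  if (any(is.na(values) & !missing))
    stop("NA value present where mask says non-missing")
  ok <- values[!missing]
  if (any(ok < 0 | ok > 100))
    stop("present values must lie in [0, 100]")
  structure(
    list(dates = dates, values = values, missing = missing,
         label = label, region = region),
    class = "weekly_series")
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("<weekly_series> %s [%s]: %d weeks, %s to %s, %.1f%% missing\n",
              x$label, x$region, length(x$values),
              format(x$dates[1]), format(x$dates[length(x$dates)]),
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
length.weekly_series <- function(x) length(x$values)

#' Monthly series
#'
#' Calendar-month-indexed series: either monthly aggregated search volumes or
#' monthly outcome counts for one stratum. Months must be contiguous and, in
#' analysis-ready form, no values are missing.
#'
#' @param year,month integer vectors (contiguous calendar months).
#' @param values numeric vector.
#' @param label series label (term or stratum name).
#' @param region region code.
#' @return An object of class \code{monthly_series}.
#' @export
monthly_series <- function(year, month, values, label = "", region = "") {
  year <- as.integer(year); month <- as.integer(month)
  values <- as.numeric(values)
  n <- length(values)
  if (length(year) != n || length(month) != n)
    stop("year, month and values must have the same length")
  if (n == 0L) stop("empty series")
  if (any(month < 1L | month > 12L)) stop("month out of range")
  idx <- year * 12L + (month - 1L)
  if (n > 1L && any(diff(idx) != 1L))
    stop("months must be contiguous")
  structure(
    list(year = year, month = month, values = values,
         label = label, region = region),
    class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<monthly_series> %s [%s]: %d months, %04d-%02d to %04d-%02d\n",
              x$label, x$region, n, x$year[1], x$month[1], x$year[n], x$month[n]))
  invisible(x)
}

#' @export
length.monthly_series <- function(x) length(x$values)

# linear (year, month) index used for alignment arithmetic
month_index <- function(m) m$year * 12L + (m$month - 1L)

#' Align two monthly series on their common span
#'
#' @param x,y \code{monthly_series}.
#' @return list with both series restricted to the overlapping months.
#' @keywords internal
align_monthly <- function(x, y) {
  ix <- month_index(x); iy <- month_index(y)
  lo <- max(ix[1], iy[1]); hi <- min(ix[length(ix)], iy[length(iy)])
  if (lo > hi) stop("series have no overlapping months")
  sx <- which(ix >= lo & ix <= hi)
  sy <- which(iy >= lo & iy <= hi)
  list(
    x = monthly_series(x$year[sx], x$month[sx], x$values[sx], x$label, x$region),
    y = monthly_series(y$year[sy], y$month[sy], y$values[sy], y$label, y$region))
}

#' Read a Google-Trends-style weekly CSV export
#'
#' Skips any preamble lines until a header whose first field is "week" (case
#' insensitive; "Week" in real exports), then reads \code{week,value} rows.
#' Blank values are missing; \code{zero_as_missing = TRUE} additionally maps
#' displayed zeros to missing, since the export conflates "0" with
#' "insufficient data".
#'
#' @param path CSV file path.
#' @param label,region metadata attached to the series.
#' @param zero_as_missing map 0 values to missing (default \code{FALSE}).
#' @return A \code{weekly_series}.
#' @export
read_weekly_csv <- function(path, label = "", region = "", zero_as_missing = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^\\s*week\\s*,", lines, ignore.case = TRUE)
  if (length(hdr) == 0L) stop("no 'week,...' header found in ", path)
  hdr <- hdr[1]
  body <- lines[seq.int(hdr + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  dates <- as.Date(vapply(parts, `[`, "", 1L))
  raw <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2L]) else "", "")
  vals <- suppressWarnings(as.numeric(raw))
  miss <- raw == "" | is.na(vals)
  if (zero_as_missing) miss <- miss | (!is.na(vals) & vals == 0)
  vals[miss] <- NA_real_
  weekly_series(dates, vals, miss, label = label, region = region)
}

#' Write a weekly series to CSV
#'
#' Writes the \code{week,value} dialect read back by
#' \code{\link{read_weekly_csv}}; missing values are written blank.
#'
#' @param x \code{weekly_series}.
#' @param path output file path.
#' @export
write_weekly_csv <- function(x, path) {
  vals <- ifelse(x$missing, "", format(x$values, trim = TRUE, scientific = FALSE))
  writeLines(c("week,value", paste(format(x$dates), vals, sep = ",")), path)
  invisible(path)
}

#' Read monthly outcome counts
#'
#' Reads a \code{year,month,stratum,count} CSV and returns one
#' \code{monthly_series} per stratum.
#'
#' @param path CSV file path.
#' @param region region code attached to each series.
#' @return Named list of \code{monthly_series}, one per stratum.
#' @export
read_monthly_counts_csv <- function(path, region = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "stratum", "count")
  if (!all(need %in% names(df))) stop("expected columns: ", paste(need, collapse = ","))
  out <- lapply(split(df, df$stratum), function(d) {
    d <- d[order(d$year * 12L + d$month), , drop = FALSE]
    monthly_series(d$year, d$month, d$count, label = d$stratum[1], region = region)
  })
  out[order(names(out))]
}

#' Write monthly outcome counts
#'
#' @param series named list of \code{monthly_series} (one per stratum), or a
#'   single \code{monthly_series}.
#' @param path output file path.
#' @export
write_monthly_counts_csv <- function(series, path) {
  if (inherits(series, "monthly_series")) series <- stats::setNames(list(series), series$label)
  rows <- do.call(rbind, lapply(names(series), function(st) {
    m <- series[[st]]
    data.frame(year = m$year, month = m$month, stratum = st, count = m$values)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
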