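#' Categorize a weekly series by data availability
#'
#' Availability falls into four mutually exclusive categories:
#' \code{complete} (no missing weeks), \code{incomplete} (some missing),
#' \code{peaks_only} (data only at isolated single peaks), and \code{no_data}.
#' "Peaks only" is operationalized as: the fraction of non-missing weeks is at
#' most \code{sparsity} and non-missing values occur in isolated runs of at
#' most \code{max_peak_run} weeks.
#'
#' @param series a \code{\link{weekly_series}}.
#' @param sparsity maximum non-missing fraction for \code{peaks_only}
#'   (default 0.10).
#' @param max_peak_run maximum run length of non-missing weeks for
#'   \code{peaks_only} (default 2).
#' @return One of \code{"complete"}, \code{"incomplete"}, \code{"peaks_only"},
#'   \code{"no_data"}.
#' @export
categorize_series <- function(series, sparsity = 0.10, max_peak_run = 2) {
  miss <- series$missing
  if (all(miss)) return("no_data")
  if (!any(miss)) return("complete")
  present_frac <- mean(!miss)
  runs <- rle(!miss)
  longest_present <- max(runs$lengths[runs$values])
  if (present_frac <= sparsity && longest_present <= max_peak_run)
    return("peaks_only")
  "incomplete"
}

#' Crop missing margins of a weekly series
#'
#' Removes leading and trailing runs of missing weeks; interior missingness is
#' untouched. Idempotent.
#'
#' @param series a \code{\link{weekly_series}}.
#' @return The cropped \code{weekly_series}.
#' @export
crop_margins <- function(series) {
  present <- which(!series$missing)
  if (length(present) == 0L)
    stop("series has no data after cropping")
  i <- present[1L]; j <- present[length(present)]
  weekly_series(series$dates[i:j], series$values[i:j], series$missing[i:j],
                label = series$label, region = series$region)
}

# calendar-month span covered by the weekly dates (weeks cover 7 days)
span_months <- function(dates) {
  first <- dates[1L]
  last <- dates[length(dates)] + 6L
  fy <- as.integer(format(first, "%Y")); fm <- as.integer(format(first, "%m"))
  ly <- as.integer(format(last, "%Y"));  lm <- as.integer(format(last, "%m"))
  (ly * 12L + lm) - (fy * 12L + fm) + 1L
}

#' Check inclusion rules for a cropped weekly series
#'
#' A series qualifies for time-series analysis if it spans at least
#' \code{min_months} calendar months, has at most \code{max_missing} missing
#' weekly values, and its longest interior missing run is at most
#' \code{max_run} weeks (about two months). The missing fraction is computed
#' on the cropped weekly series.
#'
#' @param series a cropped \code{\link{weekly_series}}.
#' @param min_months minimum span in calendar months (default 36).
#' @param max_missing maximum missing fraction (default 0.10).
#' @param max_run maximum consecutive missing weeks (default 10).
#' @return list with \code{passed}, \code{n_months},
#'   \code{missing_fraction_weekly}, \code{longest_missing_run_weeks}, and
#'   \code{reasons} (character vector of violated rules; empty iff passed).
#' @export
check_inclusion <- function(series, min_months = 36, max_missing = 0.10,
                            max_run = 10) {
  n_months <- span_months(series$dates)
  mf <- mean(series$missing)
  runs <- rle(series$missing)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  reasons <- character()
  if (n_months < min_months) reasons <- c(reasons, "min_span")
  if (mf > max_missing) reasons <- c(reasons, "max_missing")
  if (longest > max_run) reasons <- c(reasons, "max_run")
  list(passed = length(reasons) == 0L, n_months = n_months,
       missing_fraction_weekly = mf, longest_missing_run_weeks = longest,
       reasons = reasons)
}

#' Linearly interpolate interior missing weeks
#'
#' Every missing value is replaced by the linear interpolant between its
#' nearest non-missing neighbours. Margins must already be cropped.
#'
#' @param series a cropped \code{\link{weekly_series}}.
#' @return A \code{weekly_series} with no missing values.
#' @export
interpolate_weekly <- function(series) {
  if (series$missing[1L] || series$missing[length(series$missing)])
    stop("marginal missing values present; crop_margins() first")
  if (!any(series$missing)) return(series)
  v <- series$values
  v <- stats::approx(which(!series$missing), v[!series$missing],
                     xout = seq_along(v), method = "linear")$y
  weekly_series(series$dates, v, rep(FALSE, length(v)),
                label = series$label, region = series$region)
}

#' Aggregate a weekly series to monthly resolution by calendar weighting
#'
#' Each calendar month's value is the average of the overlapping weekly
#' values, weighted by the number of each week's seven days that fall in the
#' month. Margin months covered by fewer than \code{min_days} days are
#' dropped, so that no month is estimated from a sliver of data.
#'
#' @param series a fully interpolated \code{\link{weekly_series}}.
#' @param min_days minimum days of coverage for a margin month (default 15).
#' @return A \code{\link{monthly_series}}.
#' @export
aggregate_to_monthly <- function(series, min_days = 15) {
  if (any(series$missing)) stop("interpolate before aggregating")
  # each week covers dates[w] .. dates[w]+6 and straddles at most two months
  d0 <- series$dates
  d6 <- d0 + 6L
  ym0 <- as.integer(format(d0, "%Y")) * 12L + as.integer(format(d0, "%m")) - 1L
  ym6 <- as.integer(format(d6, "%Y")) * 12L + as.integer(format(d6, "%m")) - 1L
  straddle <- ym0 != ym6
  # days of the week remaining in the start month when it straddles
  first_next <- as.Date(sprintf("%04d-%02d-01", ym6 %/% 12L, ym6 %% 12L + 1L))
  w_first <- ifelse(straddle, as.integer(first_next - d0), 7L)
  months <- c(ym0, ym6[straddle])
  weights <- c(w_first, 7L - w_first[straddle])
  wvals <- c(series$values, series$values[straddle])
  num <- tapply(wvals * weights, months, sum)
  den <- tapply(weights, months, sum)
  idx <- as.integer(names(num))
  ord <- order(idx)
  idx <- idx[ord]
  vals <- as.numeric(num / den)[ord]
  den <- as.numeric(den)[ord]
  keep <- rep(TRUE, length(idx))
  if (den[1L] < min_days) keep[1L] <- FALSE
  if (den[length(den)] < min_days) keep[length(keep)] <- FALSE
  idx <- idx[keep]; vals <- vals[keep]
  if (length(idx) == 0L) stop("no month with sufficient coverage")
  monthly_series(idx %/% 12L, idx %% 12L + 1L, vals,
                 label = series$label, region = series$region)
}

#' Prepare a raw weekly series for analysis
#'
#' Applies the fixed preprocessing order: crop missing margins, categorize,
#' check the inclusion rules, linearly interpolate interior gaps, and
#' aggregate to monthly resolution with calendar weighting.
#'
#' @param series a raw \code{\link{weekly_series}}.
#' @param ... passed to \code{\link{check_inclusion}}.
#' @return list with \code{category}, \code{inclusion} (the rule report),
#'   \code{weekly} (cropped, interpolated) and \code{monthly} (\code{NULL}
#'   when the series is excluded).
#' @export
prepare_series <- function(series, ...) {
  category <- categorize_series(series)
  if (category == "no_data")
    return(list(category = category, inclusion = NULL, weekly = NULL, monthly = NULL))
  cropped <- crop_margins(series)
  inc <- check_inclusion(cropped, ...)
  if (!inc$passed || category == "peaks_only")
    return(list(category = category, inclusion = inc, weekly = cropped, monthly = NULL))
  interp <- interpolate_weekly(cropped)
  list(category = category, inclusion = inc, weekly = interp,
       monthly = aggregate_to_monthly(interp))
}
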