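#' Build a rectangular pull matrix from repeated pulls
#'
#' Aligns repeated pulls of the same nominal series on the intersection of
#' their dates (pulls made on different days are asynchronous) and drops time
#' points that are missing in any pull, yielding the complete
#' time-points-by-pulls matrix required by the intraclass correlation.
#'
#' @param pulls list of at least two \code{\link{weekly_series}}.
#' @return Numeric matrix, rows = time points, columns = pulls, with
#'   attributes \code{dates}, \code{label}, \code{region}.
#' @export
pull_matrix <- function(pulls) {
  if (length(pulls) < 2L) stop("need at least 2 pulls")
  common <- Reduce(intersect, lapply(pulls, function(p) as.integer(p$dates)))
  if (length(common) == 0L) stop("pulls share no dates")
  common <- sort(common)
  cols <- lapply(pulls, function(p) p$values[match(common, as.integer(p$dates))])
  m <- do.call(cbind, cols)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 complete time points across pulls")
  attr(m, "dates") <- as.Date(common[keep], origin = "1970-01-01")
  attr(m, "label") <- pulls[[1L]]$label
  attr(m, "region") <- pulls[[1L]]$region
  m
}

#' Intraclass correlation (two-way, consistency) of repeated pulls
#'
#' Quantifies pull-to-pull agreement with the consistency-type intraclass
#' correlation from a two-way ANOVA with time points as rows and pulls as
#' columns: ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E) for single pulls
#' and ICC(C,k) = (MS_R - MS_E) / MS_R for the k-pull average (the algebra is
#' identical under the two-way random and two-way mixed models). Confidence
#' intervals come from the F ratio MS_R / MS_E with (n-1, (n-1)(k-1)) degrees
#' of freedom, transformed to the ICC scale. Negative estimates are reported,
#' not truncated.
#'
#' @param m numeric matrix (rows = time points, columns = pulls), e.g. from
#'   \code{\link{pull_matrix}}; n >= 3 rows, k >= 2 columns, no missing cells.
#' @param alpha two-sided confidence level is \code{1 - alpha} (default .05).
#' @return list with \code{icc_single}, \code{icc_average}, \code{ci_single},
#'   \code{ci_average}, \code{n}, \code{k}, \code{alpha}.
#' @export
icc_consistency <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need n >= 3 time points and k >= 2 pulls")
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_e == 0 && ms_r == 0) stop("zero variance: ICC undefined")
  icc1 <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  icck <- (ms_r - ms_e) / ms_r
  f <- ms_r / ms_e
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (is.finite(f)) {
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci1 <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    cik <- c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    ci1 <- cik <- c(1, 1)  # zero residual variance: agreement is exact
  }
  list(icc_single = icc1, icc_average = icck,
       ci_single = ci1, ci_average = cik,
       n = n, k = k, alpha = alpha)
}

#' Average repeated pulls into a consensus series
#'
#' Pointwise arithmetic mean of the aligned pulls (inner join on dates). A
#' time point is marked missing when the fraction of pulls missing there
#' exceeds \code{na_tolerance}; otherwise the mean of the present values is
#' used. Averaging repeated pulls raises reliability according to the
#' Spearman-Brown relation.
#'
#' @param pulls list of at least two \code{\link{weekly_series}}.
#' @param na_tolerance maximum tolerated fraction of missing pulls per time
#'   point (default 0: any missing pull makes the point missing).
#' @return A \code{\link{weekly_series}}.
#' @export
average_pulls <- function(pulls, na_tolerance = 0) {
  if (length(pulls) < 2L) stop("need at least 2 pulls")
  common <- Reduce(intersect, lapply(pulls, function(p) as.integer(p$dates)))
  if (length(common) == 0L) stop("pulls share no dates")
  common <- sort(common)
  m <- do.call(cbind, lapply(pulls, function(p)
    p$values[match(common, as.integer(p$dates))]))
  frac_na <- rowMeans(is.na(m))
  vals <- rowMeans(m, na.rm = TRUE)
  miss <- frac_na > na_tolerance | is.nan(vals)
  vals[miss] <- NA_real_
  weekly_series(as.Date(common, origin = "1970-01-01"), vals, miss,
                label = pulls[[1L]]$label, region = pulls[[1L]]$region)
}

#' Spearman-Brown step-up of a single-measure reliability
#'
#' @param icc_single single-measure ICC.
#' @param k number of averaged measurements.
#' @return The k-average reliability \code{k * icc / (1 + (k - 1) * icc)}.
#' @export
spearman_brown <- function(icc_single, k) {
  k * icc_single / (1 + (k - 1) * icc_single)
}
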