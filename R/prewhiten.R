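#' Prewhiten an explanatory/dependent series pair
#'
#' Filters the explanatory series by its own fitted model to obtain
#' (approximate) white-noise innovations, and passes the dependent series
#' through the identical filter -- same differencing, same ARMA coefficients,
#' frozen, with no re-estimation -- so that cross-correlations between the
#' filtered pair cannot be inflated by autocorrelation or trend shared by
#' construction. Outlier effects estimated for the explanatory series are
#' removed from it before filtering and are \emph{not} applied to the
#' dependent series (they are interventions specific to the search-volume
#' record). Filtering is exact: each series is passed through the Kalman
#' filter of the frozen model (all coefficients fixed, nothing re-estimated),
#' so the innovations carry no warm-up transient; undifferenced models center
#' each series by its own mean. The first \code{d + D s} values (differencing
#' initialization) are dropped from both series, keeping them aligned.
#'
#' @param x explanatory \code{\link{monthly_series}} the model was fitted on.
#' @param y dependent \code{\link{monthly_series}}; must overlap \code{x} on
#'   at least \code{min_overlap} months.
#' @param model \code{fitted_model} for \code{x}.
#' @param min_overlap minimum common months (default 36).
#' @return An object of class \code{prewhitened_pair}: \code{x_innovations},
#'   \code{y_filtered}, \code{year}/\code{month} index, \code{model_used}.
#' @export
prewhiten <- function(x, y, model, min_overlap = 36) {
  if (length(x) != model$n)
    stop("model was not fitted on x (length mismatch)")
  spec <- model$spec
  xv <- x$values
  # subtract estimated outlier effects from x
  if (length(model$outliers) > 0L) {
    xr <- outlier_xreg(length(xv), model$outliers, io_ref = model)
    for (j in seq_along(model$outliers)) {
      nm <- colnames(xr)[j]
      w <- model$coefficients$estimate[model$coefficients$term == nm]
      if (length(w) == 1L) xv <- xv - w * xr[, j]
    }
  }
  x_adj <- monthly_series(x$year, x$month, xv, x$label, x$region)
  al <- align_monthly(x_adj, y)
  if (length(al$x) < min_overlap)
    stop("insufficient overlap between x and y")
  cl <- model$coefficients_list
  fixed <- c(cl$ar, cl$ma, cl$sar, cl$sma)
  filt <- function(v) {
    if (spec$d == 0 && spec$D == 0) v <- v - mean(v)
    f <- stats::arima(v, order = c(spec$p, spec$d, spec$q),
                      seasonal = list(order = c(spec$P, spec$D, spec$Q),
                                      period = spec$s),
                      include.mean = FALSE, transform.pars = FALSE,
                      fixed = if (length(fixed) > 0) fixed else NULL)
    as.numeric(stats::residuals(f))
  }
  ex <- filt(al$x$values)
  ey <- filt(al$y$values)
  drop_front <- spec$d + spec$D * spec$s
  if (length(ex) <= drop_front + 8L) stop("series too short after filtering")
  keep <- seq.int(drop_front + 1L, length(ex))
  idx <- keep
  structure(
    list(x_innovations = ex[keep], y_filtered = ey[keep],
         year = al$x$year[idx], month = al$x$month[idx],
         model_used = spec, x_label = x$label, y_label = y$label,
         region = x$region),
    class = "prewhitened_pair")
}

#' @export
print.prewhitened_pair <- function(x, ...) {
  cat(sprintf("<prewhitened_pair> %s ~ %s: %d months, filter SARIMA%s\n",
              x$x_label, x$y_label, length(x$x_innovations),
              format(x$model_used)))
  invisible(x)
}

#' Cross-correlation function of a prewhitened pair
#'
#' Pearson cross-correlations at lags \code{-max_lag .. +max_lag}. The sign
#' convention is pinned to the forecasting interpretation: a \emph{negative}
#' lag k pairs the explanatory series at month t with the dependent series
#' |k| months \emph{later} ("x leads y"); a positive lag pairs x at t with y
#' |k| months earlier. Note that library CCF conventions differ; this one is
#' chosen so that forecasting-relevant associations sit at negative lags.
#' Significance bands are \code{qnorm(1 - alpha/2) / sqrt(n_pairs)} with the
#' per-lag pair count \code{n - |k|}.
#'
#' @param pair a \code{\link{prewhiten}} result (or any list with
#'   \code{x_innovations} and \code{y_filtered}).
#' @param max_lag maximum lag in months (default 3).
#' @param alpha two-sided significance level for the bands (default .05).
#' @return An object of class \code{ccf_result}: data frame with columns
#'   \code{lag}, \code{r}, \code{n_pairs}, \code{band}, \code{significant}.
#' @export
ccf_prewhitened <- function(pair, max_lag = 3, alpha = 0.05) {
  ex <- pair$x_innovations; ey <- pair$y_filtered
  n <- length(ex)
  if (max_lag < 1) stop("max_lag must be >= 1")
  if (n <= max_lag + 2L) stop("series too short for the requested lags")
  lags <- seq.int(-max_lag, max_lag)
  r <- n_pairs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k <= 0) {
      a <- ex[seq_len(n - abs(k))]
      b <- ey[seq.int(abs(k) + 1L, n)]
    } else {
      a <- ex[seq.int(k + 1L, n)]
      b <- ey[seq_len(n - k)]
    }
    n_pairs[i] <- length(a)
    r[i] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
            else stats::cor(a, b)
  }
  band <- stats::qnorm(1 - alpha / 2) / sqrt(n_pairs)
  out <- data.frame(lag = lags, r = r, n_pairs = n_pairs, band = band,
                    significant = !is.na(r) & abs(r) > band)
  structure(list(table = out, x_label = pair$x_label, y_label = pair$y_label,
                 region = pair$region, alpha = alpha),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> %s ~ %s [%s]\n", x$x_label, x$y_label, x$region))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Lead/lag interpretation of a cross-correlation result
#'
#' Labels each significant lag: negative lags mean the explanatory
#' (search-volume) series leads the outcome -- the forecasting-relevant
#' direction; positive lags mean the outcome led later searching; lag zero
#' is coincident and carries no information on temporal precedence.
#' Non-significant lags are labelled null.
#'
#' @param result a \code{\link{ccf_prewhitened}} result.
#' @return data frame with columns \code{lag}, \code{label}
#'   (\code{x_leads_y} / \code{y_leads_x} / \code{coincident} / \code{null})
#'   and \code{sign} (-1, 0, +1).
#' @export
classify_lags <- function(result) {
  tb <- result$table
  lab <- ifelse(!tb$significant, "null",
         ifelse(tb$lag < 0, "x_leads_y",
         ifelse(tb$lag > 0, "y_leads_x", "coincident")))
  sgn <- ifelse(tb$significant, sign(tb$r), 0)
  data.frame(lag = tb$lag, label = lab, sign = sgn)
}
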