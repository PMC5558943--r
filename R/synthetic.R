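#' Generator specification for synthetic search-volume series
#'
#' Describes a weekly (or monthly) normalized search-volume generator with
#' seasonal ARIMA dynamics, 0-100 normalization, missingness, outlier events
#' and pull-to-pull noise. The generated processes stand in for Google-Trends
#' exports so that every downstream stage (preprocessing, reliability, model
#' selection, prewhitened cross-correlation) can be tested against known
#' structure.
#'
#' @param arima_orders integer 6-vector (p, d, q, P, D, Q).
#' @param season_length season length in observations (12 for monthly
#'   seasonality; 52 approximates yearly seasonality in weekly data).
#' @param coefficients list with optional elements \code{ar}, \code{ma},
#'   \code{sar}, \code{sma} (numeric vectors, \code{stats::arima} sign
#'   convention). AR/seasonal-AR polynomials must be stationary, MA
#'   polynomials invertible.
#' @param innovation_sd positive innovation standard deviation.
#' @param n_weeks series length.
#' @param missing_fraction fraction of weeks set missing, in [0, 1).
#' @param max_missing_run longest permitted missing run (weeks).
#' @param outlier_events list of \code{list(position=, type="IO"|"AO",
#'   magnitude=)} with magnitude in innovation-SD units. AO contaminates one
#'   observation; IO contaminates one innovation so the shock propagates
#'   through the dynamics.
#' @param pull_noise_sd non-negative SD of pull-to-pull noise, on the latent
#'   (pre-normalization) scale.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An object of class \code{gen_spec}.
#' @export
gen_spec <- function(arima_orders = c(1, 0, 0, 0, 0, 0), season_length = 12,
                     coefficients = list(ar = 0.5), innovation_sd = 1,
                     n_weeks = 200, missing_fraction = 0, max_missing_run = 10,
                     outlier_events = list(), pull_noise_sd = 0, seed = 1) {
  arima_orders <- as.integer(arima_orders)
  stopifnot(length(arima_orders) == 6L, all(arima_orders >= 0L),
            season_length >= 1, innovation_sd > 0, n_weeks >= 1,
            missing_fraction >= 0, missing_fraction < 1,
            max_missing_run >= 1, pull_noise_sd >= 0)
  names(arima_orders) <- c("p", "d", "q", "P", "D", "Q")
  pol <- sarima_polys(arima_orders, coefficients, season_length, include_diff = FALSE)
  if (!roots_outside_unit(pol$ar))
    stop("AR/seasonal-AR polynomial is not stationary")
  if (!roots_outside_unit(pol$ma))
    stop("MA/seasonal-MA polynomial is not invertible")
  stopifnot(length(coefficients$ar %||% numeric()) == arima_orders[1L],
            length(coefficients$ma %||% numeric()) == arima_orders[3L],
            length(coefficients$sar %||% numeric()) == arima_orders[4L],
            length(coefficients$sma %||% numeric()) == arima_orders[6L])
  m_target <- round(missing_fraction * n_weeks)
  m_max <- n_weeks - max(0L, ceiling((n_weeks - max_missing_run) / (max_missing_run + 1)))
  if (m_target > m_max)
    stop(sprintf("missing_fraction %.2f with max_missing_run %d is unsatisfiable for n_weeks %d",
                 missing_fraction, max_missing_run, n_weeks))
  for (ev in outlier_events) {
    stopifnot(ev$position >= 1, ev$position <= n_weeks, ev$type %in% c("IO", "AO"))
  }
  structure(
    list(arima_orders = arima_orders, season_length = as.integer(season_length),
         coefficients = coefficients, innovation_sd = innovation_sd,
         n_weeks = as.integer(n_weeks), missing_fraction = missing_fraction,
         max_missing_run = as.integer(max_missing_run),
         outlier_events = outlier_events, pull_noise_sd = pull_noise_sd,
         seed = as.integer(seed)),
    class = "gen_spec")
}

# latent (pre-normalization, pre-missingness) path with outliers applied
gen_latent_path <- function(spec, n = spec$n_weeks, burn = NULL) {
  s <- spec$season_length
  if (is.null(burn)) burn <- 50L + 3L * s
  e <- stats::rnorm(burn + n, 0, spec$innovation_sd)
  for (ev in spec$outlier_events)
    if (ev$type == "IO") e[burn + ev$position] <- e[burn + ev$position] +
        ev$magnitude * spec$innovation_sd
  z <- recolor_innovations(e, spec$arima_orders, spec$coefficients, s)
  z <- tail_keep(z, n)
  for (ev in spec$outlier_events)
    if (ev$type == "AO") z[ev$position] <- z[ev$position] +
        ev$magnitude * spec$innovation_sd
  list(values = z, innovations = e, burn = burn)
}

# min-max scale to 0..100 and round, as Google Trends displays
normalize_0_100 <- function(z) {
  z <- z - min(z)
  mx <- max(z)
  if (mx == 0) return(rep(100L, length(z)))
  as.integer(round(z / mx * 100))
}

# place `m` missing weeks with no run longer than max_run (uniform rejection)
draw_missing_mask <- function(n, m, max_run) {
  mask <- rep(FALSE, n)
  if (m == 0L) return(mask)
  run_len <- function(msk, i) {
    l <- 1L; j <- i - 1L
    while (j >= 1L && msk[j]) { l <- l + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= n && msk[j]) { l <- l + 1L; j <- j + 1L }
    l
  }
  placed <- 0L; tries <- 0L
  while (placed < m) {
    tries <- tries + 1L
    if (tries > 200L * m)
      stop("could not satisfy missingness constraints")
    i <- sample.int(n, 1L)
    if (mask[i]) next
    mask[i] <- TRUE
    if (run_len(mask, i) > max_run) mask[i] <- FALSE else placed <- placed + 1L
  }
  mask
}

#' Generate one synthetic weekly search-volume series
#'
#' Simulates the latent seasonal-ARIMA path, applies the configured IO/AO
#' outlier events before normalization, min-max scales to the 0-100 integer
#' display convention, and injects missingness subject to the run-length cap.
#'
#' @param spec a \code{\link{gen_spec}}.
#' @param start_date first week start date (a Sunday by convention).
#' @param label,region metadata for the series.
#' @return A \code{\link{weekly_series}} whose maximum present value is 100.
#' @export
generate_search_series <- function(spec, start_date = as.Date("2004-01-04"),
                                   label = "synthetic", region = "SYN") {
  set.seed(spec$seed)
  path <- gen_latent_path(spec)
  vals <- as.numeric(normalize_0_100(path$values))
  m <- round(spec$missing_fraction * spec$n_weeks)
  mask <- draw_missing_mask(spec$n_weeks, m, spec$max_missing_run)
  vals[mask] <- NA_real_
  weekly_series(seq(as.Date(start_date), by = 7, length.out = spec$n_weeks),
                vals, mask, label = label, region = region)
}

#' Generate repeated noisy pulls of one latent series
#'
#' Emulates requesting the same series on different days: each pull adds
#' independent Gaussian noise of SD \code{pull_noise_sd} to the shared latent
#' path before its own 0-100 re-normalization. Larger noise yields lower
#' downstream intraclass correlation.
#'
#' @param spec a \code{\link{gen_spec}}.
#' @param k number of pulls (>= 2).
#' @inheritParams generate_search_series
#' @return List of \code{k} \code{\link{weekly_series}} sharing one
#'   missingness mask.
#' @export
generate_pulls <- function(spec, k, start_date = as.Date("2004-01-04"),
                           label = "synthetic", region = "SYN") {
  if (k < 2) stop("k must be >= 2")
  set.seed(spec$seed)
  path <- gen_latent_path(spec)
  m <- round(spec$missing_fraction * spec$n_weeks)
  mask <- draw_missing_mask(spec$n_weeks, m, spec$max_missing_run)
  dates <- seq(as.Date(start_date), by = 7, length.out = spec$n_weeks)
  lapply(seq_len(k), function(i) {
    z <- path$values + stats::rnorm(spec$n_weeks, 0, spec$pull_noise_sd)
    vals <- as.numeric(normalize_0_100(z))
    vals[mask] <- NA_real_
    weekly_series(dates, vals, mask, label = label, region = region)
  })
}

#' Transfer-effect specification
#'
#' Describes a cross-lagged association to inject between an explanatory
#' search-volume series and a monthly outcome-count series. The construction
#' guarantees that the population prewhitened cross-correlation equals
#' \code{target_ccf} at exactly \code{lag} and zero elsewhere.
#'
#' @param target_ccf population cross-correlation in (-1, 1).
#' @param lag integer in -3..3; negative lags mean the search series leads the
#'   outcome.
#' @param outcome_mean_level expected monthly count (positive).
#' @param noise_model \code{"gaussian"} (default; exact affine count mapping)
#'   or \code{"poisson"} (log-link sampling).
#' @return An object of class \code{transfer_spec}.
#' @export
transfer_spec <- function(target_ccf = 0, lag = 0, outcome_mean_level = 100,
                          noise_model = c("gaussian", "poisson")) {
  noise_model <- match.arg(noise_model)
  stopifnot(abs(target_ccf) < 1, lag >= -3, lag <= 3, outcome_mean_level > 0)
  structure(list(target_ccf = target_ccf, lag = as.integer(lag),
                 outcome_mean_level = outcome_mean_level,
                 noise_model = noise_model),
            class = "transfer_spec")
}

#' Generate a synthetic monthly explanatory series
#'
#' Monthly counterpart of \code{\link{generate_search_series}} (no
#' normalization or missingness): a seasonal-ARIMA path at monthly resolution,
#' carrying its innovation history so that \code{\link{generate_outcome_series}}
#' can construct an outcome with a known cross-lagged association.
#'
#' @param spec a \code{\link{gen_spec}} with \code{season_length = 12};
#'   \code{n_weeks} is read as the number of months.
#' @param start_year,start_month calendar origin.
#' @param label,region metadata.
#' @return A \code{\link{monthly_series}} with attributes \code{innovations},
#'   \code{burn} and \code{gen}.
#' @export
generate_monthly_series <- function(spec, start_year = 2004, start_month = 1,
                                    label = "synthetic", region = "SYN") {
  set.seed(spec$seed)
  path <- gen_latent_path(spec)
  n <- spec$n_weeks
  ym <- (start_year * 12L + start_month - 1L) + seq_len(n) - 1L
  out <- monthly_series(ym %/% 12L, ym %% 12L + 1L, path$values,
                        label = label, region = region)
  attr(out, "innovations") <- path$innovations
  attr(out, "burn") <- path$burn
  attr(out, "gen") <- spec
  out
}

#' Generate a monthly outcome series with an injected transfer effect
#'
#' Shared-filter construction: the outcome's innovation at month m is
#' \code{target_ccf} times the explanatory innovation at month \code{m + lag}
#' plus \code{sqrt(1 - target_ccf^2)} times independent noise, recolored with
#' the explanatory model's own ARMA filter and mapped to counts. With
#' \code{target_ccf = 0} the outcome is fully independent of the explanatory
#' series (the null construction used for Type-I-error calibration).
#'
#' @param x a monthly series from \code{\link{generate_monthly_series}} (must
#'   carry its innovation history).
#' @param transfer a \code{\link{transfer_spec}}.
#' @param seed integer seed for the independent noise component (use a seed
#'   unrelated to the one that generated \code{x}).
#' @param label stratum label for the outcome series.
#' @return A \code{\link{monthly_series}} of monthly counts.
#' @export
generate_outcome_series <- function(x, transfer, seed, label = "total") {
  e_x <- attr(x, "innovations")
  spec <- attr(x, "gen")
  if (is.null(e_x) || is.null(spec))
    stop("x must carry innovation history (see generate_monthly_series)")
  n <- length(x)
  N <- length(e_x)
  rho <- transfer$target_ccf
  set.seed(as.integer(seed))
  eta <- stats::rnorm(N, 0, spec$innovation_sd)
  shifted <- rep(0, N)
  lg <- transfer$lag  # negative: x leads y, e_y[m] ~ e_x[m + lg]
  src <- seq_len(N) + lg
  ok <- src >= 1L & src <= N
  shifted[ok] <- e_x[src[ok]]
  e_y <- rho * shifted + sqrt(1 - rho^2) * eta
  z <- tail_keep(recolor_innovations(e_y, spec$arima_orders, spec$coefficients,
                                     spec$season_length), n)
  mu <- transfer$outcome_mean_level
  zs <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
  counts <- switch(transfer$noise_model,
    gaussian = mu + 0.1 * mu * zs,
    poisson  = stats::rpois(n, mu * exp(0.1 * zs - 0.005)))
  monthly_series(x$year, x$month, counts, label = label, region = x$region)
}

#' Generate an explanatory/outcome pair with known transfer structure
#'
#' Convenience wrapper: one synthetic monthly explanatory series plus one
#' outcome series with the requested injected association. The outcome's
#' noise seed is derived deterministically from \code{seed} but decoupled from
#' the explanatory stream.
#'
#' @param spec a \code{\link{gen_spec}} (monthly; \code{n_weeks} = months).
#' @param transfer a \code{\link{transfer_spec}}.
#' @param seed integer; overrides \code{spec$seed}.
#' @return list with elements \code{x} and \code{y} (\code{monthly_series}).
#' @export
generate_transfer_pair <- function(spec, transfer, seed = spec$seed) {
  spec$seed <- as.integer(seed)
  x <- generate_monthly_series(spec)
  y <- generate_outcome_series(x, transfer, seed = as.integer(seed) + 500003L)
  list(x = x, y = y)
}
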