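#' Seasonal ARIMA model specification
#'
#' Orders (p,d,q)(P,D,Q)_s of a candidate model for a monthly series.
#'
#' @param p,d,q non-seasonal AR order, differencing degree, MA order.
#' @param P,D,Q seasonal counterparts.
#' @param s season length (12 for monthly data).
#' @return An object of class \code{arima_spec}.
#' @export
arima_spec <- function(p = 0, d = 0, q = 0, P = 0, D = 0, Q = 0, s = 12) {
  ords <- as.integer(c(p, d, q, P, D, Q))
  stopifnot(all(ords >= 0L), d + D <= 2, s >= 1)
  structure(list(p = ords[1L], d = ords[2L], q = ords[3L],
                 P = ords[4L], D = ords[5L], Q = ords[6L], s = as.integer(s)),
            class = "arima_spec")
}

#' @export
format.arima_spec <- function(x, ...) {
  base <- sprintf("(%d,%d,%d)", x$p, x$d, x$q)
  if (x$P + x$D + x$Q > 0) paste0(base, sprintf("(%d,%d,%d)[%d]", x$P, x$D, x$Q, x$s))
  else base
}

#' @export
print.arima_spec <- function(x, ...) {
  cat("<arima_spec>", format(x), "\n"); invisible(x)
}

spec_orders <- function(spec) c(spec$p, spec$d, spec$q, spec$P, spec$D, spec$Q)

n_spec_params <- function(spec) spec$p + spec$q + spec$P + spec$Q

# named coefficient list in the sarima_polys convention, from a stats::arima fit
coef_list <- function(fit, spec) {
  cf <- stats::coef(fit)
  pick <- function(prefix, k) if (k > 0) unname(cf[paste0(prefix, seq_len(k))]) else numeric()
  list(ar = pick("ar", spec$p), ma = pick("ma", spec$q),
       sar = pick("sar", spec$P), sma = pick("sma", spec$Q))
}

# psi weights of b(B)/a(B) with a, b polynomial coefficient vectors (B^0 first)
psi_weights_poly <- function(a, b, lag_max) {
  psi <- numeric(lag_max + 1L)
  for (j in 0:lag_max) {
    bj <- if (j < length(b)) b[j + 1L] else 0
    acc <- bj
    for (i in seq_len(min(j, length(a) - 1L)))
      acc <- acc - a[i + 1L] * psi[j - i + 1L]
    psi[j + 1L] <- acc
  }
  psi
}

# psi weights (MA-infinity, differencing included) of a fitted model
model_psi <- function(model, lag_max) {
  pol <- sarima_polys(spec_orders(model$spec), model$coefficients_list,
                      model$spec$s, include_diff = TRUE)
  psi_weights_poly(pol$ar, pol$ma, lag_max)
}

# pi* weights of a(B)/b(B): e_t = sum_j pi*_j y_{t-j}, pi*_0 = 1
model_pi <- function(model, lag_max) {
  pol <- sarima_polys(spec_orders(model$spec), model$coefficients_list,
                      model$spec$s, include_diff = TRUE)
  psi_weights_poly(pol$ma, pol$ar, lag_max)
}

# outlier regressor matrix on the observation scale; IO profiles need the
# psi weights of a reference coefficient set (io_ref), AO is a unit pulse
outlier_xreg <- function(n, events, io_ref = NULL) {
  if (length(events) == 0L) return(NULL)
  cols <- lapply(events, function(ev) {
    v <- numeric(n)
    if (ev$type == "AO") {
      v[ev$position] <- 1
    } else {
      if (is.null(io_ref)) stop("IO regressor needs a reference model")
      psi <- model_psi(io_ref, n - ev$position)
      v[ev$position:n] <- psi
    }
    v
  })
  x <- do.call(cbind, cols)
  colnames(x) <- vapply(events, function(ev)
    sprintf("%s_%d", ev$type, ev$position), "")
  x
}

#' Fit a (seasonal) ARIMA model, optionally with outlier regressors
#'
#' Maximum-likelihood fit of the specified model via the state-space
#' machinery of \code{stats::arima}, augmented with the package's model
#' bookkeeping: coefficient p-values from the normal approximation, AICc and
#' BIC, residuals trimmed of the differencing initialization, and the
#' adequacy diagnostics used by the automated Box-Jenkins protocol. Detected
#' outliers enter as pulse regressors (AO: a one-point pulse on the
#' observation; IO: the model's psi-weight profile, i.e. a pulse on the
#' innovation propagated through the dynamics) -- the ARIMAX form.
#'
#' @param series a \code{\link{monthly_series}} (or numeric vector).
#' @param spec an \code{\link{arima_spec}}.
#' @param outliers list of outlier events (\code{list(position=, type=,
#'   ...)}) to integrate as regressors.
#' @param io_ref fitted model whose coefficients shape IO regressor profiles;
#'   defaults to a preliminary fit of \code{spec} without regressors.
#' @param lb_lags Ljung-Box lag horizon; default \code{min(24, n/4)}.
#' @return An object of class \code{fitted_model}: spec, coefficient table,
#'   \code{sigma2}, residuals, log-likelihood, \code{aic}/\code{aicc}/
#'   \code{bic}, diagnostics, and the integrated outlier events.
#' @export
fit_sarima <- function(series, spec, outliers = list(), io_ref = NULL,
                       lb_lags = NULL) {
  y <- if (inherits(series, "monthly_series")) series$values else as.numeric(series)
  n <- length(y)
  if (n < 36 + spec$d + spec$D * spec$s)
    stop("series too short for the requested differencing")
  xreg <- NULL
  if (length(outliers) > 0L) {
    if (is.null(io_ref) && any(vapply(outliers, function(e) e$type == "IO", TRUE)))
      io_ref <- fit_sarima(y, spec, lb_lags = lb_lags)
    xreg <- outlier_xreg(n, outliers, io_ref)
  }
  include_mean <- spec$d == 0 && spec$D == 0
  fit <- stats::arima(y, order = c(spec$p, spec$d, spec$q),
                      seasonal = list(order = c(spec$P, spec$D, spec$Q),
                                      period = spec$s),
                      xreg = xreg, include.mean = include_mean,
                      method = "CSS-ML")
  cf <- stats::coef(fit)
  vc <- fit$var.coef
  se <- rep(NA_real_, length(cf))
  if (length(cf) > 0 && !is.null(vc)) {
    dv <- diag(vc)
    se <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
  }
  z <- cf / se
  pval <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se), z = unname(z), p = unname(pval),
                      stringsAsFactors = FALSE)
  n_used <- fit$nobs
  k <- length(cf) + 1L  # + innovation variance
  aic <- fit$aic
  aicc <- if (n_used - k - 1 > 0) aic + 2 * k * (k + 1) / (n_used - k - 1) else Inf
  bic <- aic + k * (log(n_used) - 2)
  offset <- spec$d + spec$D * spec$s
  resid <- as.numeric(stats::residuals(fit))
  resid <- resid[seq.int(offset + 1L, n)]
  model <- structure(
    list(spec = spec, coefficients = coefs, coefficients_list = coef_list(fit, spec),
         sigma2 = fit$sigma2, residuals = resid, resid_offset = offset,
         loglik = fit$loglik, aic = aic, aicc = aicc, bic = bic,
         n = n, n_used = n_used, n_params = length(cf),
         outliers = outliers, converged = is.null(fit$code) || fit$code == 0,
         series = y, fit = fit),
    class = "fitted_model")
  model$diagnostics <- model_diagnostics(model, lb_lags = lb_lags)
  model
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> SARIMA%s  n=%d  AICc=%.2f  BIC=%.2f\n",
              format(x$spec), x$n, x$aicc, x$bic))
  if (nrow(x$coefficients) > 0) {
    print(x$coefficients, row.names = FALSE, digits = 4)
  } else cat("  (no estimated regression/ARMA coefficients)\n")
  if (length(x$outliers) > 0)
    cat("  outliers:", paste(vapply(x$outliers, function(e)
      sprintf("%s@%d", e$type, e$position), ""), collapse = ", "), "\n")
  d <- x$diagnostics
  cat(sprintf("  params significant: %s | resid mean ok: %s | Ljung-Box p=%.3f (%s)\n",
              d$params_significant, d$resid_mean_ok, d$ljung_box_p,
              if (d$whiteness_ok) "white" else "autocorrelated"))
  invisible(x)
}

#' Ljung-Box portmanteau statistic
#'
#' Q = n (n + 2) sum_{j=1..L} r_j^2 / (n - j), referred to a chi-square
#' distribution with L - \code{fitted_params} degrees of freedom. Residual
#' whiteness holds when the statistic is not significant.
#'
#' @param residuals numeric residual series.
#' @param n_lags number of autocorrelation lags L.
#' @param fitted_params number of fitted ARMA parameters (df adjustment).
#' @return list with \code{stat}, \code{p}, \code{df}, \code{n_lags}.
#' @export
ljung_box <- function(residuals, n_lags, fitted_params = 0) {
  x <- as.numeric(residuals)
  n <- length(x)
  if (n_lags <= fitted_params) stop("n_lags must exceed fitted_params")
  if (n <= n_lags) stop("residual series shorter than the lag horizon")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  r <- vapply(seq_len(n_lags), function(j)
    sum(xc[seq.int(j + 1L, n)] * xc[seq.int(1L, n - j)]) / denom, 0)
  q <- n * (n + 2) * sum(r^2 / (n - seq_len(n_lags)))
  df <- n_lags - fitted_params
  list(stat = q, p = stats::pchisq(q, df, lower.tail = FALSE),
       df = df, n_lags = n_lags)
}

#' Adequacy diagnostics of a fitted model
#'
#' The three adequacy criteria of the modeling protocol: (1) all ARMA and
#' outlier-regressor coefficients significant at the 5 percent level
#' (intercepts are level parameters and are exempt); (2) residual mean not
#' significantly different from zero (one-sample t-test); (3) no remaining
#' residual autocorrelation (Ljung-Box not significant).
#'
#' @param model a \code{fitted_model}.
#' @param alpha significance level for all three checks (default .05).
#' @param lb_lags Ljung-Box horizon; default \code{min(24, floor(n/4))},
#'   raised when needed so the chi-square df is positive.
#' @return list with \code{params_significant}, \code{resid_mean_ok},
#'   \code{ljung_box_stat}, \code{ljung_box_p}, \code{whiteness_ok},
#'   \code{adequate}.
#' @export
model_diagnostics <- function(model, alpha = 0.05, lb_lags = NULL) {
  coefs <- model$coefficients
  test_rows <- coefs$term != "intercept"
  params_significant <- all(coefs$p[test_rows] < alpha, na.rm = FALSE)
  if (!any(test_rows)) params_significant <- TRUE
  if (any(is.na(coefs$p[test_rows]))) params_significant <- FALSE
  res <- model$residuals
  nr <- length(res)
  tm <- stats::t.test(res)
  resid_mean_ok <- tm$p.value >= alpha
  n_arma <- n_spec_params(model$spec)
  if (is.null(lb_lags)) lb_lags <- min(24L, floor(nr / 4))
  lb_lags <- max(lb_lags, n_arma + 1L)
  lb_lags <- min(lb_lags, nr - 1L)
  lb <- ljung_box(res, lb_lags, n_arma)
  list(params_significant = params_significant,
       resid_mean_ok = resid_mean_ok,
       ljung_box_stat = lb$stat, ljung_box_p = lb$p,
       whiteness_ok = lb$p >= alpha,
       adequate = params_significant && resid_mean_ok && lb$p >= alpha)
}

# one scan of the Cryer-Chan IO/AO statistics over all usable positions
outlier_scan <- function(model) {
  e <- model$residuals
  nr <- length(e)
  sigma <- sqrt(model$sigma2)
  lambda_io <- e / sigma
  pist <- model_pi(model, nr)  # pi*_0 = 1, pi*_j
  num <- numeric(nr); ssq <- numeric(nr)
  pi2_rev_cum <- cumsum(pist^2)
  for (t in seq_len(nr)) {
    h <- 0:(nr - t)
    num[t] <- sum(pist[h + 1L] * e[t + h])
    ssq[t] <- pi2_rev_cum[nr - t + 1L]
  }
  omega_ao <- num / ssq
  lambda_ao <- omega_ao * sqrt(ssq) / sigma
  list(lambda_io = lambda_io, lambda_ao = lambda_ao, omega_ao = omega_ao,
       offset = model$resid_offset)
}

#' Detect innovative and additive outliers
#'
#' Iterative outlier detection in the style of Cryer and Chan: at each pass
#' the IO statistic (standardized residual) and the AO statistic (the
#' innovation-weighted estimate of a one-point additive shift divided by its
#' standard error, via the model's pi-weights) are computed at every usable
#' time point; the largest absolute statistic is flagged if it exceeds the
#' Bonferroni critical value \code{qnorm(1 - alpha / (2 n))}, typed by the
#' larger of the two statistics, integrated into the model as an ARIMAX
#' regressor, and the adjusted model is re-scanned until nothing exceeds the
#' threshold. Positions within the differencing initialization window cannot
#' be scanned.
#'
#' @param model a converged \code{fitted_model}.
#' @param alpha per-series false-alarm level before the Bonferroni correction
#'   (default .05).
#' @param max_iter safety cap on detect-integrate passes.
#' @return list of outlier events: \code{position} (original series index),
#'   \code{type} ("IO"/"AO"), \code{statistic}, \code{magnitude}. Empty when
#'   nothing is flagged.
#' @export
detect_outliers <- function(model, alpha = 0.05, max_iter = 10) {
  events <- model$outliers
  current <- model
  for (it in seq_len(max_iter)) {
    sc <- outlier_scan(current)
    nr <- length(current$residuals)
    thresh <- stats::qnorm(1 - alpha / (2 * nr))
    # never re-flag an already integrated position
    taken <- vapply(events, function(e) as.integer(e$position), 0L)
    best <- pmax(abs(sc$lambda_io), abs(sc$lambda_ao))
    pos_orig <- seq_len(nr) + sc$offset
    best[pos_orig %in% taken] <- -Inf
    i <- which.max(best)
    if (!is.finite(best[i]) || best[i] <= thresh) break
    is_io <- abs(sc$lambda_io[i]) >= abs(sc$lambda_ao[i])
    ev <- list(position = pos_orig[i],
               type = if (is_io) "IO" else "AO",
               statistic = if (is_io) sc$lambda_io[i] else sc$lambda_ao[i],
               magnitude = if (is_io) current$residuals[i] else sc$omega_ao[i])
    events <- c(events, list(ev))
    current <- refit_with_outliers(model$series, model$spec, events,
                                   io_ref = current)
  }
  events
}

#' Refit a model with outlier events integrated (ARIMAX)
#'
#' @param series the original series (\code{monthly_series} or numeric).
#' @param spec the \code{\link{arima_spec}} to fit.
#' @param events outlier events as returned by \code{\link{detect_outliers}}.
#' @param io_ref model supplying psi-weight profiles for IO regressors.
#' @return A \code{fitted_model} with the events as regressors.
#' @export
refit_with_outliers <- function(series, spec, events, io_ref = NULL) {
  fit_sarima(series, spec, outliers = events, io_ref = io_ref)
}

#' Candidate grid for automated model selection
#'
#' @param p_max,q_max maximum non-seasonal AR/MA orders (default 4).
#' @param d_max maximum differencing (default 1).
#' @param P_max,Q_max,D_max seasonal counterparts (default 1).
#' @param s season length (default 12).
#' @param max_params maximum number of estimated ARMA parameters (default 6).
#' @return list of \code{\link{arima_spec}} candidates.
#' @export
model_grid <- function(p_max = 4, q_max = 4, d_max = 1,
                       P_max = 1, D_max = 1, Q_max = 1, s = 12,
                       max_params = 6) {
  g <- expand.grid(p = 0:p_max, d = 0:d_max, q = 0:q_max,
                   P = 0:P_max, D = 0:D_max, Q = 0:Q_max)
  g <- g[g$p + g$q + g$P + g$Q <= max_params, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i)
    arima_spec(g$p[i], g$d[i], g$q[i], g$P[i], g$D[i], g$Q[i], s))
}

# boundary / non-stationarity guard for a fitted candidate
fit_is_regular <- function(model, tol = 1e-3) {
  pol <- sarima_polys(spec_orders(model$spec), model$coefficients_list,
                      model$spec$s, include_diff = FALSE)
  model$converged &&
    is.finite(model$aicc) && is.finite(model$bic) &&
    !anyNA(model$coefficients$se) &&
    roots_outside_unit(pol$ar, tol) && roots_outside_unit(pol$ma, tol)
}

#' Automated Box-Jenkins model selection
#'
#' Surrogate of the manual identify-estimate-diagnose loop: every candidate
#' in the grid is fitted; candidates that fail to converge or sit on the
#' stationarity/invertibility boundary are dropped (with a logged reason);
#' the survivors are screened by the three adequacy criteria (significant
#' parameters, mean-zero residuals, white residuals); among adequate models
#' the one with minimal AICc wins, ties broken by fewer parameters, then
#' lower BIC, then lower AIC; simpler structure is thereby preferred. If no
#' candidate is adequate the minimal-AICc model is returned flagged
#' \code{adequate = FALSE}. Outlier detection then runs on the provisional
#' winner; any events are integrated as ARIMAX regressors and the diagnostics
#' re-evaluated on the adjusted fit.
#'
#' @param series a \code{\link{monthly_series}} (or numeric vector).
#' @param grid list of candidates from \code{\link{model_grid}}.
#' @param alpha significance level for diagnostics and outlier detection.
#' @param with_outliers run the outlier machinery on the winner (default
#'   \code{TRUE}).
#' @return The selected \code{fitted_model}, with fields \code{adequate} and
#'   \code{selection_log} (per-candidate status).
#' @export
select_model <- function(series, grid = model_grid(), alpha = 0.05,
                         with_outliers = TRUE) {
  stopifnot(length(grid) >= 1L)
  fits <- vector("list", length(grid))
  log <- data.frame(spec = vapply(grid, format, ""), status = "",
                    aicc = NA_real_, adequate = NA, stringsAsFactors = FALSE)
  for (i in seq_along(grid)) {
    m <- tryCatch(suppressWarnings(fit_sarima(series, grid[[i]])),
                  error = function(e) e)
    if (inherits(m, "error")) {
      log$status[i] <- paste("fit failed:", conditionMessage(m))
      next
    }
    if (!fit_is_regular(m)) {
      log$status[i] <- "dropped: boundary or non-convergent"
      next
    }
    fits[[i]] <- m
    log$status[i] <- "ok"
    log$aicc[i] <- m$aicc
    log$adequate[i] <- m$diagnostics$adequate
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("no candidate model could be fitted")
  cand <- fits[ok]
  adequate <- vapply(cand, function(m) m$diagnostics$adequate, TRUE)
  pool <- if (any(adequate)) cand[adequate] else cand
  key <- vapply(pool, function(m) m$aicc, 0)
  npar <- vapply(pool, function(m) m$n_params, 0L)
  bic <- vapply(pool, function(m) m$bic, 0)
  aic <- vapply(pool, function(m) m$aic, 0)
  ord <- order(key, npar, bic, aic)
  winner <- pool[[ord[1L]]]
  if (with_outliers) {
    events <- detect_outliers(winner, alpha = alpha)
    if (length(events) > length(winner$outliers))
      winner <- refit_with_outliers(winner$series, winner$spec, events,
                                    io_ref = winner)
  }
  winner$adequate <- winner$diagnostics$adequate
  winner$selection_log <- log
  winner
}
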