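#' Retained search terms of the four-country surveillance evaluation
#'
#' The inventory of search terms that survived availability screening and the
#' inclusion rules in the 2004-2012 four-country evaluation of search-volume
#' surveillance for suicide rates (USA, Germany, Austria, Switzerland), with
#' the published month counts and weekly missing-value percentages of the
#' corresponding Google Trends series. Terms requested with quotation marks
#' carry \code{quoted = TRUE} and are distinct series from their unquoted
#' counterparts.
#'
#' @return data frame with columns \code{region}, \code{term}, \code{quoted},
#'   \code{class} (pro_suicide / prevention / depression), \code{n_months},
#'   \code{missing_pct}, and a display \code{label}.
#' @export
retained_terms <- function() {
  df <- utils::read.csv(system.file("extdata", "retained_terms.csv",
                                    package = "trendccf"),
                        stringsAsFactors = FALSE)
  df$label <- ifelse(df$quoted, sprintf("\"%s\"", df$term), df$term)
  df
}

#' Analysis design: terms, outcome strata, lags
#'
#' The term-by-stratum grid over which the pipeline runs. The default strata
#' are total suicide rates, rates of younger (below the cut age) and older
#' individuals, and of older men and older women; selected terms can carry
#' extra strata (the overdose terms are additionally crossed with overall
#' male and female rates).
#'
#' @param terms data frame with columns \code{label}, \code{class},
#'   \code{region} (e.g. from \code{\link{retained_terms}}).
#' @param strata character vector of base outcome strata.
#' @param extra_strata named list mapping a term label to additional strata.
#' @param max_lag lag window half-width in months (default 3: lags -3..+3).
#' @param alpha per-coefficient significance level (default .05, uncorrected;
#'   the Type-I-error benchmark depends on uncorrected tests).
#' @param cut_age age separating younger from older suicides (default 40, the
#'   overall mean age of suicide in the evaluated registers).
#' @return An object of class \code{analysis_design}.
#' @export
analysis_design <- function(terms,
                            strata = c("total", "younger", "older",
                                       "older_men", "older_women"),
                            extra_strata = list(),
                            max_lag = 3, alpha = 0.05, cut_age = 40) {
  stopifnot(is.data.frame(terms),
            all(c("label", "class", "region") %in% names(terms)),
            all(terms$class %in% c("pro_suicide", "prevention", "depression")),
            max_lag >= 1, alpha > 0, alpha < 1)
  if (length(extra_strata) > 0)
    stopifnot(all(names(extra_strata) %in% terms$label))
  structure(list(terms = terms, strata = strata,
                 extra_strata = extra_strata, max_lag = as.integer(max_lag),
                 alpha = alpha, cut_age = cut_age),
            class = "analysis_design")
}

#' Default design of the four-country evaluation
#'
#' The 29 retained terms, the five outcome strata, and the men/women extra
#' strata for the two US overdose terms, at lags -3..+3.
#'
#' @inheritParams analysis_design
#' @return An \code{\link{analysis_design}}.
#' @export
default_design <- function(max_lag = 3, alpha = 0.05) {
  tt <- retained_terms()
  overdose <- tt$label[tt$term == "how to overdose"]
  extra <- stats::setNames(rep(list(c("men", "women")), length(overdose)),
                           overdose)
  analysis_design(tt, extra_strata = extra, max_lag = max_lag, alpha = alpha)
}

#' Number of cross-correlation coefficients in a design
#'
#' Exact arithmetic: (number of terms) x (base strata) x (number of lags)
#' plus the extra-strata cells.
#'
#' @param design an \code{\link{analysis_design}}.
#' @return integer coefficient count.
#' @export
count_grid <- function(design) {
  n_lags <- 2L * design$max_lag + 1L
  base <- nrow(design$terms) * length(design$strata) * n_lags
  extra <- sum(vapply(design$extra_strata, length, 0L)) * n_lags
  as.integer(base + extra)
}

#' Idealized expected cross-correlation pattern for a cell
#'
#' The a-priori pattern against which observed associations are compared if
#' search volumes truly forecast suicide rates: largest at lag 0, decreasing
#' in magnitude by .10 with each preceding lag, zero at positive lags;
#' positive sign for pro-suicide terms and depression, negative for
#' prevention terms. Lag-0 magnitudes by stratum: total .40, younger .50,
#' older .40, older men .50, older women .40; for the overdose terms' extra
#' strata, women .50 and men .40.
#'
#' @param term_class \code{"pro_suicide"}, \code{"prevention"} or
#'   \code{"depression"}.
#' @param stratum outcome stratum name.
#' @return list with \code{lags} (-3..0), \code{expected_r},
#'   \code{expected_sign}, \code{zero_at_positive_lags}.
#' @export
build_ideal <- function(term_class, stratum) {
  stopifnot(term_class %in% c("pro_suicide", "prevention", "depression"))
  peak <- switch(stratum,
    total = 0.40, younger = 0.50, older = 0.40,
    older_men = 0.50, older_women = 0.40,
    men = 0.40, women = 0.50,
    stop("unknown stratum: ", stratum))
  sgn <- if (term_class == "prevention") -1 else 1
  lags <- -3:0
  list(lags = lags, expected_r = sgn * (peak + 0.10 * lags),
       expected_sign = sgn, zero_at_positive_lags = TRUE)
}

#' Run the full term-by-stratum analysis grid
#'
#' For every term: select the explanatory model (automated Box-Jenkins with
#' outlier integration), then for every outcome stratum of that term:
#' prewhiten the pair, compute the cross-correlation function at the design's
#' lags, and classify the significant lags. Failures are recorded per cell,
#' not fatal. Execution order (terms in design order, base strata then extra
#' strata) is deterministic.
#'
#' @param store list with elements \code{terms} (named list of
#'   \code{\link{monthly_series}}, keyed by \code{region:label}) and
#'   \code{outcomes} (list keyed by region, each a named list of stratum
#'   \code{monthly_series}).
#' @param design an \code{\link{analysis_design}}.
#' @param grid candidate grid for \code{\link{select_model}}.
#' @param with_outliers passed to \code{\link{select_model}}.
#' @return list of cell records: \code{region}, \code{term}, \code{stratum},
#'   \code{term_class}, \code{ccf} (a \code{ccf_result} or \code{NULL}),
#'   \code{classification}, \code{model_spec}, \code{error}.
#' @export
run_grid <- function(store, design, grid = model_grid(), with_outliers = TRUE) {
  cells <- list()
  for (i in seq_len(nrow(design$terms))) {
    lab <- design$terms$label[i]
    region <- design$terms$region[i]
    cls <- design$terms$class[i]
    key <- paste(region, lab, sep = ":")
    strata <- c(design$strata, design$extra_strata[[lab]])
    x <- store$terms[[key]]
    model <- NULL
    model_err <- NULL
    if (is.null(x)) {
      model_err <- sprintf("missing term series '%s'", key)
    } else {
      model <- tryCatch(select_model(x, grid = grid, alpha = design$alpha,
                                     with_outliers = with_outliers),
                        error = function(e) NULL)
      if (is.null(model)) model_err <- "model selection failed"
    }
    for (st in strata) {
      cell <- list(region = region, term = lab, stratum = st,
                   term_class = cls, ccf = NULL, classification = NULL,
                   model_spec = if (!is.null(model)) format(model$spec),
                   error = model_err)
      y <- store$outcomes[[region]][[st]]
      if (is.null(cell$error) && is.null(y))
        cell$error <- sprintf("missing outcome series '%s:%s'", region, st)
      if (is.null(cell$error)) {
        res <- tryCatch({
          pw <- prewhiten(x, y, model)
          cc <- ccf_prewhitened(pw, max_lag = design$max_lag,
                                alpha = design$alpha)
          list(ccf = cc, classification = classify_lags(cc))
        }, error = function(e) conditionMessage(e))
        if (is.character(res)) cell$error <- res
        else { cell$ccf <- res$ccf; cell$classification <- res$classification }
      }
      cells[[length(cells) + 1L]] <- cell
    }
  }
  cells
}

# per-cell sign-weighted agreement between observed significant lags and the
# idealized pattern; +1 matched sign at an expected lag, -1 wrong sign or an
# unexpected significant positive lag; averaged over significant lags
concordance_score <- function(tb, ideal) {
  sig <- which(tb$significant & !is.na(tb$r))
  if (length(sig) == 0L) return(0)
  contrib <- vapply(sig, function(i) {
    if (tb$lag[i] > 0) return(-1)
    if (sign(tb$r[i]) == ideal$expected_sign) 1 else -1
  }, 0)
  mean(contrib)
}

#' Summarize a grid of cross-correlation results
#'
#' Pools all coefficients of the non-failed cells: share significant (overall
#' and per region, against the 5 percent chance expectation), effect-size
#' bins at the |r| boundaries .10/.30/.50 (lower-inclusive), median and IQR
#' of |r|, and the per-cell concordance with the idealized pattern.
#'
#' @param cells output of \code{\link{run_grid}}.
#' @return list of class \code{grid_summary}: \code{n_coefficients},
#'   \code{pct_significant}, \code{bin_counts} (large/medium/small/negligible),
#'   \code{median_abs_r}, \code{iqr_abs_r}, \code{per_region_pct_significant},
#'   \code{concordance} (data frame), \code{n_failed_cells}.
#' @export
summarize_cells <- function(cells) {
  ok <- Filter(function(c) is.null(c$error), cells)
  if (length(ok) == 0L) stop("no successful cells to summarize")
  rows <- do.call(rbind, lapply(ok, function(c) {
    tb <- c$ccf$table
    data.frame(region = c$region, term = c$term, stratum = c$stratum,
               lag = tb$lag, r = tb$r, significant = tb$significant,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[!is.na(rows$r), , drop = FALSE]
  a <- abs(rows$r)
  bins <- c(large = sum(a >= 0.50),
            medium = sum(a >= 0.30 & a < 0.50),
            small = sum(a >= 0.10 & a < 0.30),
            negligible = sum(a < 0.10))
  per_region <- vapply(split(rows$significant, rows$region),
                       function(s) 100 * mean(s), 0)
  conc <- do.call(rbind, lapply(ok, function(c) {
    data.frame(region = c$region, term = c$term, stratum = c$stratum,
               concordance = concordance_score(
                 c$ccf$table, build_ideal(c$term_class, c$stratum)),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(n_coefficients = nrow(rows),
         pct_significant = 100 * mean(rows$significant),
         bin_counts = bins,
         median_abs_r = stats::median(a),
         iqr_abs_r = unname(stats::quantile(a, c(0.25, 0.75))),
         per_region_pct_significant = per_region,
         concordance = conc,
         n_failed_cells = length(cells) - length(ok)),
    class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat(sprintf("<grid_summary> %d coefficients, %.2f%% significant\n",
              x$n_coefficients, x$pct_significant))
  cat(sprintf("  |r| bins: >=.50: %d, .30-.50: %d, .10-.30: %d, <.10: %d\n",
              x$bin_counts["large"], x$bin_counts["medium"],
              x$bin_counts["small"], x$bin_counts["negligible"]))
  cat(sprintf("  median |r| = %.3f, IQR = %.3f-%.3f; %d failed cells\n",
              x$median_abs_r, x$iqr_abs_r[1], x$iqr_abs_r[2], x$n_failed_cells))
  invisible(x)
}

#' Export grid results as a long-format heat-map table
#'
#' One row per (region, term, stratum, lag) with the coefficient, its band,
#' the significance flag and the lead/lag classification, in deterministic
#' order -- the data layer of the observed-pattern heat maps.
#'
#' @param cells output of \code{\link{run_grid}}.
#' @param path optional CSV output path.
#' @return The long-format data frame (invisibly when \code{path} is given).
#' @export
export_heatmap <- function(cells, path = NULL) {
  ok <- Filter(function(c) is.null(c$error), cells)
  df <- do.call(rbind, lapply(ok, function(c) {
    tb <- c$ccf$table
    data.frame(region = c$region, term = c$term, stratum = c$stratum,
               lag = tb$lag, r = tb$r, band = tb$band,
               significant = tb$significant,
               classification = classify_lags(c$ccf)$label,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Build a synthetic term-by-stratum store
#'
#' Generates a complete synthetic input for \code{\link{run_grid}}: one
#' monthly explanatory series per term and one monthly outcome-count series
#' per stratum, all mutually independent unless an injected association is
#' requested for one (term, stratum) cell.
#'
#' @param design an \code{\link{analysis_design}} (synthetic regions/terms).
#' @param spec a \code{\link{gen_spec}} template (monthly; \code{n_weeks} is
#'   the number of months).
#' @param seed integer master seed; per-series seeds are derived from it.
#' @param injected optional \code{list(term=, stratum=, transfer=)} injecting
#'   a \code{\link{transfer_spec}} association into one cell.
#' @param outcome_mean_level mean monthly count for the null outcomes.
#' @return A store list with \code{terms} and \code{outcomes}.
#' @export
synthetic_store <- function(design, spec, seed = 1, injected = NULL,
                            outcome_mean_level = 100) {
  seed <- as.integer(seed)
  terms <- list()
  null_tr <- transfer_spec(0, 0, outcome_mean_level)
  for (i in seq_len(nrow(design$terms))) {
    s <- spec; s$seed <- seed + 1000L * i
    lab <- design$terms$label[i]
    region <- design$terms$region[i]
    terms[[paste(region, lab, sep = ":")]] <-
      generate_monthly_series(s, label = lab, region = region)
  }
  outcomes <- list()
  for (region in unique(design$terms$region)) {
    strata <- unique(c(design$strata, unlist(design$extra_strata)))
    outcomes[[region]] <- stats::setNames(lapply(seq_along(strata), function(j) {
      carrier_key <- paste(region, design$terms$label[design$terms$region == region][1], sep = ":")
      inj <- !is.null(injected) && strata[j] == injected$stratum
      if (inj) {
        x <- terms[[paste(region, injected$term, sep = ":")]]
        generate_outcome_series(x, injected$transfer,
                                seed = seed + 777L * j, label = strata[j])
      } else {
        generate_outcome_series(terms[[carrier_key]], null_tr,
                                seed = seed + 777L * j, label = strata[j])
      }
    }), strata)
  }
  list(terms = terms, outcomes = outcomes)
}
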