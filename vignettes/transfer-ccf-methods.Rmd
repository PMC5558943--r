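---
title: "Evaluating search-volume surveillance with prewhitened transfer-function CCFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating search-volume surveillance with prewhitened transfer-function CCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendccf)
```

## The problem

Weekly search-volume series and monthly suicide-count series are both
strongly structured: yearly seasonality, slow trends, and serial
correlation. Any two such series will correlate to some degree for reasons
that have nothing to do with one forecasting the other. The methodology
implemented here asks the forecasting question only after removing that
shared structure: model the explanatory series with a seasonal ARIMA model,
pass **both** series through that same filter ("prewhitening"), and only
then cross-correlate. Under the null of no transfer, the filtered pair is
(approximately) a pair of independent white-noise series, and the share of
significant cross-correlations should match the nominal test level. That 5%
benchmark is the yardstick the whole evaluation leans on, so the package
treats its calibration as a first-class, tested property.

## Pipeline and assumptions

**Preprocessing.** Google-Trends-style exports report integers 0–100 per
week, with 0 doubling as "insufficient data"; missingness is therefore an
explicit mask, and a reader flag (`zero_as_missing`) maps displayed zeros to
missing. Series are cropped of missing margins, then screened: span at
least 36 calendar months, at most 10% missing weeks, no missing run longer
than 10 weeks (about two months). Interior gaps are linearly interpolated
— defensible only because the inclusion rules cap how much interpolation
can happen. Weekly values are aggregated to months by exact day-count
weighting: a week contributes to a month in proportion to how many of its
seven days fall in it. Two conventions here are ours, because the source
procedure leaves them open: the missing fraction is computed on the
*cropped* weekly series (the only reading consistent with reporting
post-crop spans), and a margin month covered by fewer than 15 days is
dropped rather than estimated from a sliver (`min_days`, configurable). The
peaks-only category is operationalized as "non-missing fraction at most 0.10
in isolated runs of at most 2 weeks" — a codification of what is, in the
field, a visual judgement; both constants are arguments.

**Reliability.** Repeated pulls of the same nominal series differ because
the provider resamples; agreement is quantified by the two-way consistency
intraclass correlation. With time points as rows and pulls as columns,
ICC(C,1) = (MS~R~ − MS~E~) / (MS~R~ + (k−1) MS~E~) and ICC(C,k) =
(MS~R~ − MS~E~) / MS~R~; the two are linked exactly by the Spearman–Brown
relation, which the tests assert to 1e−12. The source procedure does not
state its confidence-interval method; we use the standard interval from
F = MS~R~/MS~E~ with (n−1, (n−1)(k−1)) degrees of freedom and flag that as
an assumption. Negative ICCs are reported, not truncated — degenerate
inputs should look degenerate. Pulls are aligned by inner join on dates
before the ANOVA because pulls are asynchronous and the ICC needs a
rectangular matrix.

**Model selection.** The manual identify–estimate–diagnose loop is
automated as an exhaustive small-grid search: by default p,q ∈ 0..4,
d ∈ 0..1, P,D,Q ∈ 0..1, s = 12, at most 6 ARMA parameters — bounds wide
enough to contain every model the motivating application ever selected.
The pure-mean model (0,0,0) is a legitimate candidate: without it, white
noise gets described by whichever overparameterized candidate happens to
have jointly "significant" coefficients. Adequacy is the three-part
criterion: all ARMA and outlier-regressor coefficients significant at .05
(normal approximation to estimate/SE; the intercept is a level parameter
and exempt), residual mean not significantly nonzero (one-sample t-test),
and a non-significant Ljung–Box statistic, computed at L = min(24, n/4)
lags with degrees of freedom reduced by the fitted ARMA parameter count —
the horizon is our documented default, configurable, not a claim about the
source procedure. Among adequate candidates the minimal AICc wins (AICc =
AIC + 2k(k+1)/(n−k−1), k counting the innovation variance), with ties broken
by fewer parameters, then BIC, then AIC; if nothing is adequate the
minimal-AICc fit is returned flagged inadequate rather than silently
promoted. Candidates that fail to converge or land on the
stationarity/invertibility boundary (roots within 1.001 of the unit circle)
are dropped with a logged reason.

**Outliers.** Only two intervention types are modelled, matching the
framework this automates: additive outliers (one contaminated observation)
and innovative outliers (one contaminated innovation, propagating through
the dynamics). Detection scans standardized residuals (IO statistic) and
the π-weight-projected additive-shift estimate over its standard error (AO
statistic); the largest absolute statistic is flagged if it exceeds the
Bonferroni critical value z at 1 − α/(2n), typed by whichever statistic is
larger, integrated as an ARIMAX regressor (AO: unit pulse; IO: the model's
ψ-weight profile from the event onward), and the adjusted model is
re-scanned until quiet. Two numerical caveats are deliberate: residuals
from the state-space fit begin after the d + D·s differencing
initialization, so events inside that initial window are undetectable by
construction; and the IO regressor's shape is built from the coefficients of
the previous pass, the standard resolution of the circularity between
estimating the model and estimating the intervention.

**Prewhitening and the CCF.** The explanatory model's coefficients are
frozen and both series are passed through the exact Kalman filter of that
model — nothing is re-estimated for the dependent series, and the
explanatory series' outlier effects are first subtracted from it (they are
interventions in the search record, not in mortality). We filter through
the state-space machinery rather than a truncated recursive filter because
zero-initialized MA inversion leaves a slowly decaying seasonal transient
that measurably inflates the null significance rate; with exact filtering
the null calibration sits at the nominal level (the acceptance suite
measures it). Undifferenced models center each series by its own mean;
differencing removes means anyway. The first d + D·s filtered values are
initialization artifacts and are dropped from both series. Cross-correlations
use plain Pearson correlation on index-shifted pairs with per-lag counts
n − |k|, and bands z~1−α/2~/√(n−|k|) — per-lag counts are exact for the
truncated overlap and conservative. The provider-side convention trap is
pinned down loudly: **negative lag means the search series leads the
outcome**; libraries differ, and a silent sign flip reverses the scientific
conclusion. Lag-window ±3 months is the defensible psychological horizon
for search-to-behaviour coupling; wider windows are a parameter, not a
default.

**Evaluation grid.** Idealized patterns exist only at lags −3..0 with an
expected zero at positive lags, magnitudes at lag 0 of .40 (total, older,
older women, men) or .50 (younger, older men, women), shrinking by .10 per
preceding month, positive for pro-suicide and depression terms and negative
for prevention terms. The concordance score — matched significant lag with
correct sign +1, wrong sign −1, any significant positive lag −1, averaged
over significant lags — is our own construction (the comparison is visual
in the source setting); it is documented, bounded in [−1,1], and
configurable in the sense that it lives in one small function. Per-
coefficient tests run at α = .05 with no multiplicity correction: the
Type-I-error argument is *about* uncorrected tests.

## The synthetic-data generator

The generator is the package's ground truth. Weekly series are seasonal
ARIMA paths, min-max scaled to 0–100 and rounded to integers (the display
quantization is real and mildly stresses downstream fitting), with
missingness placed under the run-length cap and IO/AO events applied before
normalization. Pulls add independent Gaussian noise to the shared latent
path before each pull's own re-normalization; a noise SD of 0.7 (on the
latent scale, for the default AR(1) latent process) was calibrated by
simulation to land single-pull ICCs near .75, the reliability regime of a
small country's series, and larger noise lowers the ICC monotonically.

Cross-lagged associations use a shared-filter construction: the outcome's
innovation at month m is ρ·(explanatory innovation at month m+ℓ) +
√(1−ρ²)·(independent noise), recolored with the explanatory model's own
ARMA filter and mapped affinely to a count level (Gaussian default; a
Poisson log-link option exists for integer counts, at the price of exact
tractability — the Gaussian map is not rounded precisely so that the
population prewhitened CCF equals ρ at lag ℓ and zero elsewhere,
analytically). Defaults for the study conditions are 84 monthly
observations per series and a SARIMA(1,0,0)(0,1,1)₁₂ explanatory process
(φ = .5, Θ = −.6) — the modal model shape and series length of the
motivating application.

What the generator does **not** emulate: the provider's actual sampling
algorithm (only additive pull noise), time-varying asynchronicity between
pulls (reported to be worse for earlier years, but never quantified, so we
decline to guess), demographically differentiated search volumes, and
media-event dynamics beyond single IO/AO shocks. Passing tests therefore
demonstrate calibration and recovery *under the stated generative model*,
not validity of any substantive claim about real search data.

## Numerical choices and degenerate inputs

- Estimation is `stats::arima` (CSS-ML, Kalman filter); everything
  downstream — AICc, BIC, p-values, residual bookkeeping (exactly
  n − d − D·s residuals), π/ψ weights — is package code.
- Determinism: every stochastic routine takes or derives an explicit seed;
  identical seeds give bit-identical output, and grid execution order never
  affects a statistic.
- Zero residual variance in the ICC with nonzero row variance yields ICC 1
  with a degenerate [1,1] interval; zero variance in both directions is an
  error, not a number.
- A zero-variance window at some CCF lag yields NA for that lag rather
  than a fabricated correlation; summaries drop NAs.
- Unsatisfiable missingness requests (fraction vs. run cap) fail at
  specification time with the arithmetic bound, not at sampling time.

## Problem sizes used by the test suite

The suite validates calibration with 500 null pipeline replicates (84
months each), lag recovery with 200 replicates at ρ = .5 and power with 500
at ρ = .4, outlier machinery with 50 injection seeds per type plus 60 clean
seeds, and all oracle equivalences (daily-expansion aggregation, direct-sum
CCF, aov-based ICC, reference Ljung–Box, Spearman–Brown) at tolerances
1e−9 to 1e−12. These sizes were chosen so the binomial noise of each
estimated rate is small relative to the band it is checked against.

## Known limitations

- Outlier events inside the differencing initialization window (the first
  d + D·s points) cannot be detected.
- The adequacy screen can, on featureless data, admit overparameterized
  models whose coefficients are jointly spuriously significant; the
  pure-mean candidate and the parsimony tie-break mitigate but do not
  abolish this (it is a property of the protocol being automated).
- Seasonal AR and seasonal MA components of similar magnitude are weakly
  identified at n ≈ 84; selected models are then near-neighbours of the
  truth, which is immaterial for prewhitening (the filters are nearly
  identical) but matters if coefficients are interpreted individually.
- The F-based ICC intervals assume balanced, complete pull matrices; the
  inner-join alignment enforces completeness by discarding, which can bias
  toward the well-covered part of the record.
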