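Package: trendccf
Title: Prewhitened Transfer-Function Evaluation of Search-Volume Surveillance Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether normalized online search-volume time
    series (Google-Trends-style weekly exports) carry forecasting information
    about national mortality outcomes such as suicide rates. Implements the
    full evaluation pipeline: cropping, categorization, inclusion filtering,
    linear interpolation and calendar-weighted aggregation of weekly series to
    monthly resolution; intraclass-correlation reliability of repeated pulls of
    the same series; automated Box-Jenkins seasonal ARIMA model selection with
    innovative/additive outlier detection and ARIMAX integration; prewhitened
    cross-correlation functions at short leads and lags with significance
    bands and lead/lag interpretation; and a grid runner that compares observed
    association patterns against idealized expected patterns across outcome
    strata. A synthetic-data generator with known seasonal ARIMA structure,
    0-100 normalization, missingness, outlier events, pull noise and injectable
    cross-lagged transfer effects makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
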