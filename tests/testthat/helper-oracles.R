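# Independent oracles the implementation is checked against. These stay
# deliberately naive: daily expansion, explicit index-shifted sums, aov().

# weekly -> monthly aggregation by expanding each week into 7 daily copies
oracle_monthly_aggregate <- function(series, min_days = 15) {
  days <- as.Date(character(0)); vals <- numeric(0)
  for (w in seq_along(series$values)) {
    days <- c(days, series$dates[w] + 0:6)
    vals <- c(vals, rep(series$values[w], 7))
  }
  key <- format(days, "%Y-%m")
  agg <- sapply(split(vals, key), mean)
  cnt <- sapply(split(vals, key), length)
  keep <- rep(TRUE, length(agg))
  keep[1] <- cnt[1] >= min_days
  keep[length(keep)] <- cnt[length(cnt)] >= min_days
  agg[keep]
}

# cross-correlation at one lag by explicit summation (no cor())
oracle_ccf_at <- function(ex, ey, k) {
  n <- length(ex)
  if (k <= 0) { a <- ex[1:(n - abs(k))]; b <- ey[(abs(k) + 1):n] }
  else        { a <- ex[(k + 1):n];      b <- ey[1:(n - k)] }
  m <- length(a)
  ma <- sum(a) / m; mb <- sum(b) / m
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# two-way consistency ICC via aov() mean squares
oracle_icc <- function(m) {
  df <- data.frame(v = as.vector(m),
                   row = factor(rep(seq_len(nrow(m)), ncol(m))),
                   col = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(v ~ row + col, data = df))[[1]]
  ms_r <- tab["row", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  c(single = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e),
    average = (ms_r - ms_e) / ms_r)
}

make_weekly <- function(values, start = as.Date("2004-01-04"), label = "t") {
  weekly_series(seq(start, by = 7, length.out = length(values)),
                values, label = label, region = "SYN")
}
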