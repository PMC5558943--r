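# Polynomial machinery shared by the generator, the outlier detector and the
# prewhitening filter. Polynomials are coefficient vectors in the backshift
# operator B, constant term first: the AR operator phi(B) = 1 - sum phi_i B^i
# is stored as c(1, -phi), the MA operator theta(B) = 1 + sum theta_j B^j as
# c(1, theta).

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

seasonal_expand <- function(coefs, s) {
  # c(1, g1, g2) at season s -> coefficients of 1 + g1 B^s + g2 B^2s
  if (length(coefs) == 1L) return(coefs)
  out <- numeric((length(coefs) - 1L) * s + 1L)
  out[1L + s * (seq_along(coefs) - 1L)] <- coefs
  out
}

diff_poly <- function(d, D, s) {
  p <- 1
  if (d > 0) for (i in seq_len(d)) p <- poly_mult(p, c(1, -1))
  if (D > 0) for (i in seq_len(D)) p <- poly_mult(p, seasonal_expand(c(1, -1), s))
  p
}

# Full AR and MA operator polynomials of a (p,d,q)(P,D,Q)_s model.
# coefs: list(ar=, ma=, sar=, sma=) in the stats::arima sign convention.
sarima_polys <- function(orders, coefs, s, include_diff = TRUE) {
  ar  <- c(1, -as.numeric(coefs$ar  %||% numeric()))
  sar <- seasonal_expand(c(1, -as.numeric(coefs$sar %||% numeric())), s)
  ma  <- c(1,  as.numeric(coefs$ma  %||% numeric()))
  sma <- seasonal_expand(c(1,  as.numeric(coefs$sma %||% numeric())), s)
  ar_full <- poly_mult(ar, sar)
  if (include_diff) ar_full <- poly_mult(ar_full, diff_poly(orders[2L], orders[5L], s))
  list(ar = ar_full, ma = poly_mult(ma, sma))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all roots of poly(B) outside the unit circle (stationarity/invertibility)
roots_outside_unit <- function(poly, tol = 1e-8) {
  poly <- poly[seq_len(max(which(abs(poly) > 0)))]
  if (length(poly) <= 1L) return(TRUE)
  all(Mod(polyroot(poly)) > 1 + tol)
}

# Colour an innovation vector with the stationary ARMA part of the model, then
# apply the inverse differencing. Returns the full-length path; callers drop
# their own burn-in.
recolor_innovations <- function(innov, orders, coefs, s) {
  pol <- sarima_polys(orders, coefs, s, include_diff = FALSE)
  ma <- pol$ma
  a <- innov
  if (length(ma) > 1L)
    a <- as.numeric(stats::filter(innov, ma, method = "convolution", sides = 1))
  a[is.na(a)] <- innov[is.na(a)]  # warm-up: missing MA history treated as zero
  arp <- pol$ar
  y <- a
  if (length(arp) > 1L)
    y <- as.numeric(stats::filter(a, -arp[-1L], method = "recursive"))
  d <- orders[2L]; D <- orders[5L]
  if (d > 0) y <- tail_keep(stats::diffinv(y, differences = d), length(innov))
  if (D > 0) y <- tail_keep(stats::diffinv(y, lag = s, differences = D), length(innov))
  y
}

tail_keep <- function(x, n) x[seq.int(length(x) - n + 1L, length(x))]
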