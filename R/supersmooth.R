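# Running local-linear smoother over a symmetric truncated window of
# half-width J, with leave-one-out cross-validated residuals from the
# closed-form leverage. Window sums come from padded cumulative sums, so the
# whole fit is O(n).
smooth_ll <- function(x, y, J) {
  n <- length(x)
  J <- max(1L, as.integer(J))
  lo <- pmax(1L, seq_len(n) - J)
  hi <- pmin(n, seq_len(n) + J)
  cs <- function(v) c(0, cumsum(v))
  Sx <- cs(x); Sy <- cs(y); Sxx <- cs(x * x); Sxy <- cs(x * y)
  m <- hi - lo + 1
  sx <- Sx[hi + 1L] - Sx[lo]
  sy <- Sy[hi + 1L] - Sy[lo]
  sxx <- Sxx[hi + 1L] - Sxx[lo]
  sxy <- Sxy[hi + 1L] - Sxy[lo]
  xbar <- sx / m
  ybar <- sy / m
  vx <- sxx - sx * sx / m       # sum of squared deviations in window
  cxy <- sxy - sx * sy / m
  slope <- ifelse(vx > 1e-12, cxy / vx, 0)
  fit <- ybar + slope * (x - xbar)
  lev <- 1 / m + ifelse(vx > 1e-12, (x - xbar)^2 / vx, 0)
  denom <- pmax(1 - lev, 1e-10)
  list(fit = fit, cv_resid = (y - fit) / denom)
}

span_to_J <- function(span, n) max(2L, as.integer(floor(span * n / 2)))

#' Friedman's supersmoother (variable-span local linear smoother)
#'
#' Smooths `y` against strictly increasing `x` with local linear regression
#' whose span adapts to the data: three candidate spans (0.05, 0.2 and 0.5 of
#' the series length) are fit, leave-one-out cross-validated absolute
#' residuals choose the locally best span, the chosen spans are themselves
#' smoothed with the midrange span, fitted values are interpolated between
#' the bracketing candidate fits, and the result is passed once more through
#' the smallest span. With `bass > 0` the span choice is pushed toward the
#' largest span for a smoother result.
#'
#' With `span` given, a single fixed-span local linear fit is returned (the
#' window at position `i` is the up to `2J + 1` points `i - J .. i + J`
#' truncated at the series ends, `J = floor(span * n / 2)`).
#'
#' Series shorter than 10 points fall back to one fixed-span fit at span 0.3,
#' flagged by attribute `fallback = TRUE`.
#'
#' @param x Strictly increasing numeric predictor.
#' @param y Numeric response, same length as `x`.
#' @param span Optional fixed span in (0, 1]; `NULL` (default) selects spans
#'   by cross-validation.
#' @param bass Bass enhancement in 0..10; larger favours larger spans.
#' @return Numeric vector of smoothed values, same length as `y`.
#' @examples
#' x <- seq(0, 1, length.out = 100)
#' y <- sin(2 * pi * x) + rnorm(100, sd = 0.2)
#' s <- supersmooth(x, y)
#' @export
supersmooth <- function(x, y, span = NULL, bass = 0) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` lengths differ.", class = "foldq_error")
  if (n >= 2 && any(diff(x) <= 0)) {
    abort("`x` must be strictly increasing.", class = "foldq_error")
  }
  if (bass < 0 || bass > 10) abort("`bass` must be in 0..10.", class = "foldq_error")
  if (n < 10) {
    out <- smooth_ll(x, y, span_to_J(0.3, n))$fit
    attr(out, "fallback") <- TRUE
    return(out)
  }
  if (!is.null(span)) {
    if (span <= 0 || span > 1) abort("`span` must be in (0, 1].", class = "foldq_error")
    return(smooth_ll(x, y, span_to_J(span, n))$fit)
  }
  spans <- c(0.05, 0.2, 0.5)
  fits <- matrix(0, n, 3L)
  acvr <- matrix(0, n, 3L)
  for (k in 1:3) {
    s <- smooth_ll(x, y, span_to_J(spans[k], n))
    fits[, k] <- s$fit
    acvr[, k] <- abs(s$cv_resid)
  }
  Jmid <- span_to_J(spans[2], n)
  racvr <- apply(acvr, 2, function(r) smooth_ll(x, r, Jmid)$fit)
  best <- max.col(-racvr, ties.method = "first")
  resmin <- racvr[cbind(seq_len(n), best)]
  span_sel <- spans[best]
  if (bass > 0) {
    woofer <- pmax(racvr[, 3L], 1e-10)
    f <- resmin / woofer
    adj <- f > 0 & f < 1
    span_sel[adj] <- spans[best][adj] +
      (spans[3L] - spans[best][adj]) * f[adj]^(10 - bass)
  }
  span_sm <- smooth_ll(x, span_sel, Jmid)$fit
  span_sm <- pmin(pmax(span_sm, spans[1L]), spans[3L])
  interp <- numeric(n)
  for (i in seq_len(n)) {
    k <- findInterval(span_sm[i], spans, all.inside = TRUE)
    w <- (span_sm[i] - spans[k]) / (spans[k + 1L] - spans[k])
    interp[i] <- (1 - w) * fits[i, k] + w * fits[i, k + 1L]
  }
  smooth_ll(x, interp, span_to_J(spans[1L], n))$fit
}
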