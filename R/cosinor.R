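#' Cosinor test for 24 h rhythmicity
#'
#' Least-squares fit of `M + A cos(2 pi (t - phi) / period)` via the linear
#' parameterization `M + a cos(w t) + b sin(w t)`; the p-value is the F-test
#' of the two rhythmic terms against the constant model.
#'
#' @param time_h Observation times (h).
#' @param value Observed values.
#' @param period Tested period (h).
#' @return List with `mesor`, `amplitude`, `acrophase_h` (time of fitted
#'   peak, in `[0, period)`), `p_value`, and the underlying `lm` fit.
#' @export
#' @examples
#' t <- seq(0, 71, by = 3)
#' y <- 5 + 2 * cos(2 * pi * (t - 14) / 24)
#' cosinor_test(t, y)$acrophase_h
cosinor_test <- function(time_h, value, period = 24) {
  ok <- is.finite(time_h) & is.finite(value)
  time_h <- time_h[ok]; value <- value[ok]
  if (length(time_h) < 4) stop("cosinor requires at least 4 observations")
  w <- 2 * pi / period
  cw <- cos(w * time_h); sw <- sin(w * time_h)
  fit <- stats::lm(value ~ cw + sw)
  a <- stats::coef(fit)[["cw"]]; b <- stats::coef(fit)[["sw"]]
  amplitude <- sqrt(a^2 + b^2)
  acrophase <- (atan2(b, a) / w) %% period
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((value - mean(value))^2)
  df2 <- length(value) - 3
  if (df2 <= 0) stop("cosinor requires at least 4 observations")
  if (rss1 < .Machine$double.eps * rss0 || rss0 == 0) {
    p <- if (amplitude > sqrt(.Machine$double.eps) * max(1, abs(mean(value)))) 0 else 1
  } else {
    f <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  }
  list(mesor = unname(stats::coef(fit)[[1]]), amplitude = unname(amplitude),
       acrophase_h = unname(acrophase), p_value = p, fit = fit)
}
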