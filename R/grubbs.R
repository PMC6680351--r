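#' Critical value for the two-sided Grubbs outlier test
#'
#' Computes the critical value G_crit against which the maximum absolute
#' studentized deviation is compared. Uses the Bonferroni-adjusted Student-t
#' construction: with \eqn{t} the upper \eqn{\alpha/(2n)} quantile of a
#' Student-t distribution on \eqn{n-2} degrees of freedom,
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}}\sqrt{\frac{t^2}{n-2+t^2}}.}
#'
#' @param n sample size (>= 3).
#' @param alpha two-sided significance level.
#' @return the critical value, a single positive number.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs test requires n >= 3")
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Two-sided Grubbs test for a single outlier
#'
#' Tests whether the observation farthest from the sample mean (in units of
#' the sample standard deviation) is an outlier. At most one index is flagged
#' per call; iterate (removing the flagged value and re-testing) to screen
#' for multiple outliers.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return the integer index of the flagged outlier, or `NA_integer_` when no
#'   value exceeds the critical bound (including the degenerate zero-variance
#'   case, where no observation can be an outlier).
#' @examples
#' grubbs_outlier(c(rep(0, 9), 100))   # flags the 10th value
#' grubbs_outlier(c(-1, 0, 1))         # NA: nothing unusual
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test is not applicable for n < 3")
  if (anyNA(values)) stop("values must be finite and non-missing")
  s <- stats::sd(values)
  if (s == 0) return(NA_integer_)
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  if (g > grubbs_critical(n, alpha)) which.max(dev) else NA_integer_
}
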