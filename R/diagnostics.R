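#' Split R-hat convergence diagnostic
#'
#' Splits each chain in half and computes the Gelman-Rubin potential
#' scale-reduction factor over the resulting sequences:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}}
#' with W the mean within-sequence variance and B the between-sequence
#' variance (n the split-half length). Values near 1 indicate the chains
#' have mixed; splitting also detects within-chain drift.
#'
#' @param draws matrix of draws, iterations x chains (>= 2 chains or >= 4
#'   iterations of one chain, so that at least two split halves exist).
#' @return R-hat; `Inf` when the within-sequence variance is zero (constant
#'   chains).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) stop("split R-hat needs >= 4 iterations per chain")
  half <- floor(n / 2)
  halves <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  if (m < 2) stop("split R-hat needs >= 2 sequences")
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0) return(Inf)
  B <- half * stats::var(colMeans(halves))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Equal-tailed credible interval from posterior draws
#'
#' Empirical quantiles at (1-level)/2 and 1-(1-level)/2 under the
#' linear-interpolation quantile convention.
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param level interval mass, e.g. 0.80 or 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' credible_interval(1:100, 0.80)  # c(10.9, 90.1)
#' @export
credible_interval <- function(draws, level = 0.95) {
  stopifnot(length(draws) >= 2, level > 0, level < 1)
  unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                         type = 7, names = FALSE))
}

#' Posterior summary table
#'
#' Mean, median, 80% and 95% equal-tailed credible bounds and split R-hat
#' for every parameter of a draws array.
#'
#' @param draws iterations x chains x parameters array.
#' @param rhat optional pre-computed R-hat vector (computed if missing).
#' @return data frame with columns parameter, mean, median, lo80, hi80,
#'   lo95, hi95, rhat.
#' @export
posterior_summary <- function(draws, rhat = NULL) {
  pars <- dimnames(draws)[[3]]
  if (is.null(rhat)) rhat <- apply(draws, 3, split_rhat)
  rows <- lapply(seq_along(pars), function(j) {
    x <- as.vector(draws[, , j])
    ci80 <- credible_interval(x, 0.80)
    ci95 <- credible_interval(x, 0.95)
    data.frame(parameter = pars[j], mean = mean(x),
               median = stats::median(x),
               lo80 = ci80[1], hi80 = ci80[2],
               lo95 = ci95[1], hi95 = ci95[2],
               rhat = rhat[j])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
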