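#' Fit the three-level hierarchical model of eDNA copy numbers
#'
#' Gibbs sampler for the nested normal model on the log10 scale:
#' replicate observations are Normal(point mean, sigma_point^2); point means
#' are Normal(transect mean, sigma_transect^2); transect means at the
#' telemetry site are Normal(beta0 + beta1 * count, sigma_telemetry^2) where
#' `count` is the day's number of unique telemetry detections; transect
#' means at other sites share a per-site level m_site with a fixed
#' Normal(m_site, site_mean_sd^2) spread. Priors: beta0, beta1 and each
#' m_site are Normal(0, beta_sd^2); each variance is
#' inverse-gamma(sigma_shape, sigma_rate). Every full conditional is
#' conjugate, so the sampler is a plain Gibbs scan.
#'
#' Chains start from data-derived values (empirical point/transect means, a
#' least-squares slope) jittered per chain to overdisperse the starting
#' points; each chain uses a seed derived deterministically from `seed`.
#' Convergence is summarised by split R-hat ([split_rhat()]); any value
#' above 1.1 triggers a warning but results are still returned.
#'
#' Variance components may be fixed via `sigma_fixed` (e.g. for oracle
#' comparisons). Fixing both `point` and `transect` at 0 collapses the model
#' to a transect-level Bayesian regression: each transect's response is the
#' mean of its observations and only beta0, beta1, sigma_telemetry and the
#' site levels are sampled.
#'
#' @param data a `hier_data` from [prepare_hier_data()].
#' @param n_chains,n_warmup,n_sampling MCMC size (defaults 4 chains of
#'   1000 + 1000; heavier than the minimal 4 x 80 + 80 configuration this
#'   model is known to tolerate, which remains available by argument).
#' @param seed master RNG seed.
#' @param priors list overriding any of `beta_mean`, `beta_sd`,
#'   `sigma_shape`, `sigma_rate`, `site_mean_sd`.
#' @param sigma_fixed list with optional fixed values for `point`,
#'   `transect`, `telemetry` standard deviations (NULL = sampled).
#' @param keep_latent which latent means to store: `"all"` (point and
#'   transect), `"transect"`, or `"none"` (top-level parameters only).
#' @return object of class `hier_posterior`: `draws` (iteration x chain x
#'   parameter array), `rhat`, `summary` (mean, median, 80% and 95%
#'   credible bounds, rhat per parameter), MCMC sizes, and metadata
#'   (`log_offset`, seed, fixed sigmas).
#' @export
fit_hierarchical <- function(data, n_chains = 4, n_warmup = 1000,
                             n_sampling = 1000, seed = 1,
                             priors = list(),
                             sigma_fixed = list(point = NULL, transect = NULL,
                                                telemetry = NULL),
                             keep_latent = c("all", "transect", "none")) {
  stopifnot(inherits(data, "hier_data"), n_chains >= 1, n_sampling >= 2)
  keep_latent <- match.arg(keep_latent)
  pr <- utils::modifyList(list(beta_mean = 0, beta_sd = 10,
                               sigma_shape = 0.01, sigma_rate = 0.01,
                               site_mean_sd = 10), priors)

  fix_p <- sigma_fixed$point
  fix_t <- sigma_fixed$transect
  fix_e <- sigma_fixed$telemetry
  zero_p <- !is.null(fix_p) && fix_p == 0
  zero_t <- !is.null(fix_t) && fix_t == 0
  if (xor(zero_p, zero_t))
    stop("collapsed configuration requires fixing both sigma_point and ",
         "sigma_transect at 0, or neither")
  collapsed <- zero_p && zero_t

  has_c <- !is.na(data$count)
  n_cov <- sum(has_c)
  if (n_cov < 2 || length(unique(data$count[has_c])) < 2)
    warning("telemetry slope is not identified (fewer than 2 distinct ",
            "covariate values); its posterior reflects the prior")

  chains <- lapply(seq_len(n_chains), function(ch) {
    chain_seed <- (seed + 7919 * (ch - 1)) %% 2147483647
    if (collapsed)
      gibbs_chain_collapsed(data, n_warmup, n_sampling, chain_seed, pr, fix_e)
    else
      gibbs_chain_full(data, n_warmup, n_sampling, chain_seed, pr,
                       fix_p, fix_t, fix_e, keep_latent)
  })
  par_names <- colnames(chains[[1]])
  draws <- array(unlist(chains, use.names = FALSE),
                 dim = c(n_sampling, length(par_names), n_chains))
  draws <- aperm(draws, c(1, 3, 2))
  dimnames(draws) <- list(NULL, paste0("chain", seq_len(n_chains)), par_names)

  rhat <- apply(draws, 3, function(m) split_rhat(m))
  if (any(is.finite(rhat) & rhat > 1.1))
    warning("possible non-convergence: split R-hat > 1.1 for ",
            paste(par_names[which(is.finite(rhat) & rhat > 1.1)],
                  collapse = ", "))

  structure(list(
    draws = draws, rhat = rhat,
    summary = posterior_summary(draws, rhat),
    n_chains = n_chains, n_warmup = n_warmup, n_sampling = n_sampling,
    seed = seed, log_offset = data$log_offset,
    sigma_fixed = sigma_fixed, collapsed = collapsed
  ), class = "hier_posterior")
}

#' @export
print.hier_posterior <- function(x, ...) {
  cat("Hierarchical eDNA model posterior:", x$n_chains, "chains x",
      x$n_sampling, "sampling iterations (", x$n_warmup, "warmup )\n")
  top <- x$summary[!grepl("^mu_", x$summary$parameter), ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

# One Gibbs chain over the full three-level model. Returns a matrix of
# sampling-phase draws (iterations x parameters).
gibbs_chain_full <- function(d, n_warmup, n_sampling, chain_seed, pr,
                             fix_p, fix_t, fix_e, keep_latent) {
  set.seed(chain_seed)
  y <- d$y
  N <- length(y)
  P <- nrow(d$points)
  Tt <- nrow(d$transects)
  t_of_p <- d$transect_of_point
  s_of_t <- d$site_of_transect
  has_c <- !is.na(d$count)
  cnt <- d$count[has_c]
  Xc <- cbind(1, cnt)
  n_sites_nc <- length(unique(s_of_t[!has_c]))
  site_ids_nc <- sort(unique(s_of_t[!has_c]))
  s_nc <- match(s_of_t[!has_c], site_ids_nc)   # site index of each nc transect

  sum_y_p <- as.vector(rowsum(y, d$point))
  n_p <- tabulate(d$point, P)
  k_t <- tabulate(t_of_p, Tt)
  T_s <- tabulate(s_nc, n_sites_nc)

  # data-derived starting values, jittered per chain
  ybar_p <- sum_y_p / n_p
  mu_t <- as.vector(rowsum(ybar_p, t_of_p)) / k_t
  jit <- 2 * max(stats::sd(y), 0.1)
  mu_p <- ybar_p + stats::runif(P, -jit, jit)
  mu_t <- mu_t + stats::runif(Tt, -jit, jit)
  s2p <- if (is.null(fix_p)) max(stats::var(y - ybar_p[d$point]), 0.01) *
    exp(stats::runif(1, -1, 1)) else fix_p^2
  s2t <- if (is.null(fix_t)) max(stats::var(ybar_p - mu_t[t_of_p]), 0.01) *
    exp(stats::runif(1, -1, 1)) else fix_t^2
  s2e <- if (is.null(fix_e)) max(stats::var(mu_t), 0.01) *
    exp(stats::runif(1, -1, 1)) else fix_e^2
  beta <- c(mean(y), 0) + stats::runif(2, -2, 2) * pr$beta_sd
  m_site <- rep(mean(y), n_sites_nc) + stats::runif(n_sites_nc, -jit, jit)

  a0 <- pr$sigma_shape; b0 <- pr$sigma_rate
  v_beta <- pr$beta_sd^2
  v_site <- pr$site_mean_sd^2

  par_names <- c("telemetry_intercept", "telemetry_slope",
                 "sigma_point", "sigma_transect", "sigma_telemetry",
                 if (n_sites_nc) paste0("m_", d$sites[site_ids_nc]),
                 if (keep_latent %in% c("all", "transect"))
                   paste0("mu_t[", d$transects$transect, "]"),
                 if (keep_latent == "all")
                   paste0("mu_p[", d$points$key, "]"))
  out <- matrix(NA_real_, n_sampling, length(par_names),
                dimnames = list(NULL, par_names))

  pm <- numeric(Tt)
  pv <- numeric(Tt)
  pv[has_c] <- NA  # set each iteration
  for (it in seq_len(n_warmup + n_sampling)) {
    # point means | y, transect means, variances
    prec_p <- n_p / s2p + 1 / s2t
    mu_p <- stats::rnorm(P, (sum_y_p / s2p + mu_t[t_of_p] / s2t) / prec_p,
                         sqrt(1 / prec_p))

    # transect means | point means, regression / site level
    pm[has_c] <- beta[1] + beta[2] * cnt
    pv[has_c] <- s2e
    if (n_sites_nc) {
      pm[!has_c] <- m_site[s_nc]
      pv[!has_c] <- v_site
    }
    sum_mup_t <- as.vector(rowsum(mu_p, t_of_p))
    prec_t <- k_t / s2t + 1 / pv
    mu_t <- stats::rnorm(Tt, (sum_mup_t / s2t + pm / pv) / prec_t,
                         sqrt(1 / prec_t))

    # regression coefficients | covariate transect means
    V_inv <- crossprod(Xc) / s2e + diag(1 / v_beta, 2)
    bm <- solve(V_inv, crossprod(Xc, mu_t[has_c]) / s2e +
                  pr$beta_mean / v_beta)
    beta <- as.vector(bm + backsolve(chol(V_inv), stats::rnorm(2)))

    # site levels for transects without a covariate
    if (n_sites_nc) {
      prec_s <- T_s / v_site + 1 / v_beta
      sum_mut_s <- as.vector(rowsum(mu_t[!has_c], s_nc))
      m_site <- stats::rnorm(n_sites_nc,
                             (sum_mut_s / v_site + pr$beta_mean / v_beta) /
                               prec_s,
                             sqrt(1 / prec_s))
    }

    # variance components | the rest
    if (is.null(fix_p))
      s2p <- 1 / stats::rgamma(1, a0 + N / 2,
                               rate = b0 + 0.5 * sum((y - mu_p[d$point])^2))
    if (is.null(fix_t))
      s2t <- 1 / stats::rgamma(1, a0 + P / 2,
                               rate = b0 + 0.5 * sum((mu_p - mu_t[t_of_p])^2))
    if (is.null(fix_e))
      s2e <- 1 / stats::rgamma(1, a0 + sum(has_c) / 2,
                               rate = b0 + 0.5 *
                                 sum((mu_t[has_c] - pm[has_c])^2))

    if (it > n_warmup) {
      row <- c(beta[1], beta[2], sqrt(s2p), sqrt(s2t), sqrt(s2e),
               if (n_sites_nc) m_site,
               if (keep_latent %in% c("all", "transect")) mu_t,
               if (keep_latent == "all") mu_p)
      out[it - n_warmup, ] <- row
    }
  }
  out
}

# Collapsed configuration: sigma_point = sigma_transect = 0, so each
# transect mean is observed directly as the mean of its observations.
gibbs_chain_collapsed <- function(d, n_warmup, n_sampling, chain_seed, pr,
                                  fix_e) {
  set.seed(chain_seed)
  t_of_obs <- d$transect_of_point[d$point]
  Tt <- nrow(d$transects)
  y_t <- as.vector(rowsum(d$y, t_of_obs)) / tabulate(t_of_obs, Tt)
  s_of_t <- d$site_of_transect
  has_c <- !is.na(d$count)
  cnt <- d$count[has_c]
  Xc <- cbind(1, cnt)
  y_c <- y_t[has_c]
  site_ids_nc <- sort(unique(s_of_t[!has_c]))
  n_sites_nc <- length(site_ids_nc)
  s_nc <- match(s_of_t[!has_c], site_ids_nc)
  T_s <- tabulate(s_nc, n_sites_nc)

  a0 <- pr$sigma_shape; b0 <- pr$sigma_rate
  v_beta <- pr$beta_sd^2
  v_site <- pr$site_mean_sd^2

  beta <- c(mean(y_t), 0) + stats::runif(2, -2, 2) * pr$beta_sd
  s2e <- if (is.null(fix_e)) max(stats::var(y_t), 0.01) *
    exp(stats::runif(1, -1, 1)) else fix_e^2

  par_names <- c("telemetry_intercept", "telemetry_slope",
                 "sigma_point", "sigma_transect", "sigma_telemetry",
                 if (n_sites_nc) paste0("m_", d$sites[site_ids_nc]))
  out <- matrix(NA_real_, n_sampling, length(par_names),
                dimnames = list(NULL, par_names))
  for (it in seq_len(n_warmup + n_sampling)) {
    V_inv <- crossprod(Xc) / s2e + diag(1 / v_beta, 2)
    bm <- solve(V_inv, crossprod(Xc, y_c) / s2e + pr$beta_mean / v_beta)
    beta <- as.vector(bm + backsolve(chol(V_inv), stats::rnorm(2)))
    if (n_sites_nc) {
      prec_s <- T_s / v_site + 1 / v_beta
      sum_y_s <- as.vector(rowsum(y_t[!has_c], s_nc))
      m_site <- stats::rnorm(n_sites_nc,
                             (sum_y_s / v_site + pr$beta_mean / v_beta) /
                               prec_s, sqrt(1 / prec_s))
    }
    if (is.null(fix_e))
      s2e <- 1 / stats::rgamma(1, a0 + length(y_c) / 2,
                               rate = b0 + 0.5 *
                                 sum((y_c - Xc %*% beta)^2))
    if (it > n_warmup)
      out[it - n_warmup, ] <- c(beta[1], beta[2], 0, 0, sqrt(s2e),
                                if (n_sites_nc) m_site)
  }
  out
}
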