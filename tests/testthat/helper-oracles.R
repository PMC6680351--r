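# Independent oracles used across the suite. Each is a brute-force or
# closed-form route that never touches the implementation it checks.

# Upper quantile of the Student-t distribution by numeric integration of a
# hand-written density (independent of stats::qt).
oracle_t_upper_quantile <- function(p_upper, df) {
  dens <- function(t) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  upper_tail <- function(x) {
    stats::integrate(dens, x, Inf, rel.tol = 1e-10)$value
  }
  stats::uniroot(function(x) upper_tail(x) - p_upper,
                 lower = 0, upper = 1e6, tol = 1e-10)$root
}

# Exact posterior moments for Bayesian linear regression with independent
# priors beta ~ N(0, v0 I), sigma^2 ~ IG(a0, b0): 1-D quadrature over
# sigma^2 of the closed-form conditional posterior of beta.
oracle_semiconj_regression <- function(y, X, v0 = 100, a0 = 0.01, b0 = 0.01,
                                       n_grid = 4000) {
  n <- length(y)
  log_marg <- function(s2) {
    S <- s2 * diag(n) + v0 * tcrossprod(X)
    ch <- chol(S)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
  }
  s2_grid <- exp(seq(log(1e-4), log(stats::var(y) * 50), length.out = n_grid))
  lw <- vapply(s2_grid, function(s2) {
    (-a0 - 1) * log(s2) - b0 / s2 + log_marg(s2) + log(s2)  # + log jacobian
  }, numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  cond <- lapply(s2_grid, function(s2) {
    V <- solve(crossprod(X) / s2 + diag(1 / v0, ncol(X)))
    list(m = as.vector(V %*% crossprod(X, y) / s2), V = V)
  })
  m_mat <- t(vapply(cond, `[[`, numeric(ncol(X)), "m"))
  e_beta <- colSums(w * m_mat)
  v_cond <- Reduce(`+`, Map(function(c_i, w_i) w_i * c_i$V, cond, w))
  v_mean <- colSums(w * sweep(m_mat, 2, e_beta)^2)
  list(beta_mean = e_beta,
       beta_sd = sqrt(diag(v_cond) + v_mean),
       sigma_mean = sum(w * sqrt(s2_grid)))
}

# Dense-grid posterior of (beta0, beta1) for a tiny nested-normal instance
# with all variance components fixed: the latent point/transect means are
# marginalised analytically into the observation covariance.
oracle_grid_beta1 <- function(y, count_of_obs, transect_of_obs, point_of_obs,
                              s_p, s_t, s_e, v0 = 100,
                              b0_grid, b1_grid) {
  n <- length(y)
  same_t <- outer(transect_of_obs, transect_of_obs, "==")
  same_p <- outer(point_of_obs, point_of_obs, "==")
  Sigma <- s_p^2 * diag(n) + s_t^2 * same_p + s_e^2 * same_t
  Sinv <- solve(Sigma)
  loglik <- function(b0, b1) {
    r <- y - (b0 + b1 * count_of_obs)
    -0.5 * as.numeric(t(r) %*% Sinv %*% r) - 0.5 * (b0^2 + b1^2) / v0
  }
  ll <- outer(b0_grid, b1_grid, Vectorize(loglik))
  p <- exp(ll - max(ll))
  p1 <- colSums(p)
  p1 / sum(p1)
}

# Brute-force grid maximisation of the identity-link Poisson likelihood,
# with two refinement passes to pin the optimum down to ~1e-5.
oracle_glm_grid_mle <- function(y, q, b0_range, b1_range, n_grid = 81,
                                passes = 4) {
  ll <- function(b0, b1) {
    mu <- b0 + b1 * q
    if (any(mu <= 0)) return(-Inf)
    sum(stats::dpois(y, mu, log = TRUE))
  }
  for (pass in seq_len(passes)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
    b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
    val <- outer(b0s, b1s, Vectorize(ll))
    idx <- arrayInd(which.max(val), dim(val))
    step0 <- diff(b0_range) / (n_grid - 1)
    step1 <- diff(b1_range) / (n_grid - 1)
    b0_range <- b0s[idx[1]] + c(-2, 2) * step0
    b1_range <- b1s[idx[2]] + c(-2, 2) * step1
  }
  c(b0s[idx[1]], b1s[idx[2]])
}

# Kolmogorov-Smirnov distance between draws and a discrete grid CDF.
ks_to_grid <- function(draws, grid, grid_pmf) {
  cdf <- cumsum(grid_pmf)
  f <- stats::approxfun(grid, cdf, yleft = 0, yright = 1, rule = 2)
  x <- sort(draws)
  ec <- seq_along(x) / length(x)
  max(abs(ec - f(x)))
}

# Small fixture: noiseless standards on the published calibration line.
clean_standards <- function(a = 41.61, b = -3.266, reps = 2) {
  copies <- rep(10^(1:6), reps)
  data.frame(known_copies = copies, ct = a + b * log10(copies))
}
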