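test_that("noiseless standards recover the generating calibration line", {
  cv <- fit_standard_curve(clean_standards())
  expect_equal(cv$intercept, 41.61, tolerance = 1e-9)
  expect_equal(cv$slope, -3.266, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  expect_equal(cv$n_used, 12)
  expect_equal(nrow(cv$excluded), 0)
  expect_false(cv$slope_nonnegative)
})

test_that("zero-copy, non-amplifying and early-Ct standards are excluded", {
  st <- rbind(clean_standards(),
              data.frame(known_copies = c(0, 1e7, 1e4),
                         ct = c(NA, 14.0, NA)))
  cv <- fit_standard_curve(st)
  expect_equal(cv$intercept, 41.61, tolerance = 1e-9)
  expect_setequal(cv$excluded$reason,
                  c("zero-standard", "below-ct-threshold", "no-amplification"))
  # boundary: Ct exactly at the threshold is excluded (strict > rule)
  st2 <- rbind(clean_standards(),
               data.frame(known_copies = 1e8, ct = 15))
  cv2 <- fit_standard_curve(st2)
  expect_true("below-ct-threshold" %in% cv2$excluded$reason)
})

test_that("a planted outlier is removed by the residual Grubbs screen and
           the refit equals the clean fit", {
  st <- clean_standards()
  st$ct[7] <- st$ct[7] + 10
  cv <- fit_standard_curve(st)
  expect_equal(cv$excluded$reason, "grubbs-outlier")
  expect_equal(cv$excluded$.row, 7)
  expect_equal(cv$intercept, 41.61, tolerance = 1e-9)
  expect_equal(cv$slope, -3.266, tolerance = 1e-9)
})

test_that("exclusion monotonicity: adding excluded points never moves the fit", {
  set.seed(42)
  st <- clean_standards()
  st$ct <- st$ct + rnorm(12, 0, 0.2)
  base <- fit_standard_curve(st)
  st_plus <- rbind(st, data.frame(known_copies = c(0, 1e9), ct = c(NA, 10)))
  aug <- fit_standard_curve(st_plus)
  expect_equal(aug$intercept, base$intercept)
  expect_equal(aug$slope, base$slope)
  expect_equal(aug$r_squared, base$r_squared)
})

test_that("fewer than three usable standards is an error", {
  st <- data.frame(known_copies = c(10, 100, 0, 1000),
                   ct = c(38, 35, NA, NA))
  expect_error(fit_standard_curve(st), "insufficient standards")
})

test_that("Grubbs test matches the t-quantile construction and flags only
           genuine outliers", {
  # critical value cross-checked against numeric integration of a
  # hand-written t density
  n <- 10; alpha <- 0.05
  t_orc <- oracle_t_upper_quantile(alpha / (2 * n), df = n - 2)
  g_orc <- ((n - 1) / sqrt(n)) * sqrt(t_orc^2 / (n - 2 + t_orc^2))
  expect_equal(grubbs_critical(n, alpha), g_orc, tolerance = 1e-7)

  expect_identical(grubbs_outlier(c(-1, 0, 1)), NA_integer_)
  x <- c(rep(0, 9), 100)
  g <- (100 - mean(x)) * 9 / 10 / sd(x) # studentized deviation by hand
  expect_gt(max(abs(x - mean(x))) / sd(x), g_orc)
  expect_identical(grubbs_outlier(x), 10L)
  expect_identical(grubbs_outlier(rep(3, 5)), NA_integer_)  # zero SD
  expect_error(grubbs_outlier(c(1, 2)), "n < 3")
})

test_that("Ct values invert through the published curve", {
  curve <- list(intercept = 41.61, slope = -3.266)
  expect_equal(ct_to_copies(41.61, curve), 1.0)
  expect_equal(ct_to_copies(41.61 - 3.266, curve), 10.0)
  expect_equal(ct_to_copies(NA, curve), 0)
  expect_error(ct_to_copies(30, list(intercept = 40, slope = 2)),
               "slope must be negative")
})

test_that("plate simulation and quantification round-trip exactly without noise", {
  copies <- 10^runif(20, 0, 6)
  plate <- simulate_qpcr_plate(copies, 41.61, -3.266, ct_noise_sd = 0)
  curve <- list(intercept = 41.61, slope = -3.266)
  expect_equal(ct_to_copies(plate$ct, curve), copies, tolerance = 1e-9)
  # zero-copy wells carry the no-amplification marker
  p0 <- simulate_qpcr_plate(c(0, 100), ct_noise_sd = 0)
  expect_true(is.na(p0$ct[1]))
  expect_false(is.na(p0$ct[2]))
  # planted outlier offset is exact when noise-free
  po <- simulate_qpcr_plate(rep(1000, 3), ct_noise_sd = 0,
                            outlier_offset = 5, outlier_indices = 2)
  expect_equal(po$ct[2] - po$ct[1], 5)
})

test_that("amplification efficiency follows the closed form", {
  expect_equal(amplification_efficiency(-1 / log10(2)), 1.0)
  expect_equal(amplification_efficiency(-3.266), 10^(1 / 3.266) - 1)
  expect_equal(amplification_efficiency(-2), 10^0.5 - 1)
  expect_error(amplification_efficiency(2), "negative slope")
})

test_that("r-squared is invariant to rescaling the copies axis labels", {
  set.seed(7)
  st <- clean_standards()
  st$ct <- st$ct + rnorm(12, 0, 0.3)
  st2 <- st
  st2$known_copies <- st2$known_copies * 1000  # affine shift on log10 axis
  expect_equal(fit_standard_curve(st)$r_squared,
               fit_standard_curve(st2)$r_squared)
})

test_that("duplicate reactions stay as separate replicate rows and controls
           are reported apart", {
  curve <- list(intercept = 41.61, slope = -3.266)
  plate <- data.frame(
    well = c("A1", "A2", "B1", "B2"),
    sample_type = c("unknown", "unknown", "ntc", "field_control"),
    known_copies = NA, site = c("Americus", "Americus", NA, NA),
    date = c(150, 150, NA, NA), point = c(3, 3, NA, NA),
    replicate = c(1, 2, NA, NA),
    ct = c(41.61 - 3.266, 41.61 - 3.266, NA, NA))
  qs <- quantify_samples(plate, curve)
  expect_equal(nrow(qs$survey), 2)
  expect_equal(qs$survey$copies, c(10, 10))
  expect_false(qs$contamination)
  # a contaminated field control raises the flag but the run continues
  plate$ct[4] <- 39
  expect_warning(qs2 <- quantify_samples(plate, curve), "amplified")
  expect_true(qs2$contamination)
  expect_equal(nrow(qs2$survey), 2)
  # controls-only plate gives an empty survey, no error
  only_ctl <- plate[plate$sample_type != "unknown", ]
  only_ctl$ct <- NA_real_
  expect_silent(qs3 <- quantify_samples(only_ctl, curve))
  expect_equal(nrow(qs3$survey), 0)
  # an unknown well without a sample key is a named error
  bad <- plate; bad$site[1] <- NA
  expect_error(quantify_samples(bad, curve), "A1")
})
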