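#' Configuration of a synthetic eDNA study
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults reproduce the shape of the Wabash River study design: three
#' sites sampled daily over 25 days (Julian days 149-173), one cross-river
#' transect of 18 evenly spaced points per site per day, two qPCR replicate
#' reactions per water sample, telemetry counts at one designated site, a
#' bimodal hydrograph (flood peaks on days 154 and 166 reaching 892 and
#' 954 m^3/s over a ~110 m^3/s base flow), and nested log10 copy numbers
#' with replicate/point/transect standard deviations (0.5, 0.3, 0.4).
#'
#' @param n_sites,n_days,points_per_transect,replicates_per_point design
#'   counts (all >= 1).
#' @param telemetry_intercept,telemetry_slope regression of transect-level
#'   log10 copies on the daily count of unique detections (log10 copies and
#'   log10 copies per fish).
#' @param sigma_point,sigma_transect,sigma_telemetry standard deviations of
#'   replicates about point means, point means about transect means, and
#'   transect means about the regression (log10 copies, >= 0).
#' @param site_baseline transect-level mean (log10 copies) for sites
#'   without telemetry.
#' @param glm_intercept,glm_slope identity-link Poisson mean of daily
#'   telemetry counts: lambda = intercept + slope * discharge.
#' @param curve_intercept,curve_slope,ct_noise_sd qPCR layer: Ct =
#'   intercept + slope * log10(copies) + Normal(0, ct_noise_sd) (slope < 0).
#' @param base_flow,peaks,flow_noise_sd hydrograph: base flow (m^3/s), a
#'   data frame `day`/`height`/`width` of Gaussian flood bumps (height is
#'   the peak excess over base flow), and day-to-day noise.
#' @param start_day first Julian day of the study window.
#' @param dropout_prob probability that a site-day survey is missing
#'   (unsafe river conditions); default 0.
#' @param rng_seed master seed; per-component streams are derived from it.
#' @return validated list of class `study_config`.
#' @export
study_config <- function(n_sites = 3, n_days = 25, points_per_transect = 18,
                         replicates_per_point = 2,
                         telemetry_intercept = 2.0, telemetry_slope = 1.0,
                         sigma_point = 0.5, sigma_transect = 0.3,
                         sigma_telemetry = 0.4, site_baseline = 2.0,
                         glm_intercept = 1.0, glm_slope = 0.004,
                         curve_intercept = 41.61, curve_slope = -3.266,
                         ct_noise_sd = 0.3,
                         base_flow = 110,
                         peaks = data.frame(day = c(154, 166),
                                            height = c(782, 844),
                                            width = c(3, 3)),
                         flow_noise_sd = 10, start_day = 149,
                         dropout_prob = 0, rng_seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_sites, n_days, points_per_transect, replicates_per_point)
  if (any(counts < 1)) stop("invalid config: all design counts must be >= 1")
  if (any(c(sigma_point, sigma_transect, sigma_telemetry, ct_noise_sd,
            flow_noise_sd) < 0))
    stop("invalid config: standard deviations must be >= 0")
  if (curve_slope >= 0) stop("invalid config: curve_slope must be < 0")
  if (base_flow <= 0) stop("invalid config: base_flow must be > 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("invalid config: dropout_prob must be in [0, 1)")
  structure(cfg, class = "study_config")
}

# Deterministic per-component RNG streams from one master seed.
derive_seed <- function(seed, component) {
  offsets <- c(hydrograph = 11, telemetry = 23, survey = 37, plate = 53,
               eggs = 71)
  (seed * 97 + offsets[[component]]) %% 2147483647
}

#' Simulate a daily hydrograph with flood peaks
#'
#' Base flow plus Gaussian flood bumps plus day-to-day Gaussian noise,
#' floored at 5% of base flow so discharge stays positive.
#'
#' @param base_flow base discharge (m^3/s, > 0).
#' @param peaks data frame with columns `day`, `height` (peak excess over
#'   base flow, m^3/s) and `width` (Gaussian SD, days); may have 0 rows.
#' @param noise_sd day-to-day noise SD (m^3/s).
#' @param n_days number of days (>= 1).
#' @param seed RNG seed.
#' @param start_day Julian day of the first value.
#' @return data frame `day`, `discharge_m3s`.
#' @export
simulate_hydrograph <- function(base_flow, peaks = NULL, noise_sd = 0,
                                n_days, seed = 1, start_day = 149) {
  if (base_flow <= 0 || n_days < 1)
    stop("invalid config: base_flow must be > 0 and n_days >= 1")
  set.seed(seed %% 2147483647)
  day <- start_day + seq_len(n_days) - 1
  q <- rep(base_flow, n_days)
  if (!is.null(peaks) && nrow(peaks)) {
    if (any(peaks$width <= 0)) stop("invalid config: peak widths must be > 0")
    for (i in seq_len(nrow(peaks)))
      q <- q + peaks$height[i] *
        exp(-0.5 * ((day - peaks$day[i]) / peaks$width[i])^2)
  }
  q <- q + stats::rnorm(n_days, 0, noise_sd)
  data.frame(day = day, discharge_m3s = pmax(q, 0.05 * base_flow))
}

#' Simulate daily unique-detection telemetry counts
#'
#' Independent Poisson draws with identity-link mean
#' lambda_d = intercept + slope * discharge_d.
#'
#' @param discharge data frame `day`, `discharge_m3s`.
#' @param glm_intercept,glm_slope mean-model coefficients; every day's mean
#'   must be positive.
#' @param seed RNG seed.
#' @return data frame `day`, `unique_detections`.
#' @export
simulate_telemetry_counts <- function(discharge, glm_intercept, glm_slope,
                                      seed = 1) {
  lambda <- glm_intercept + glm_slope * discharge$discharge_m3s
  if (any(lambda <= 0))
    stop("invalid config: non-positive Poisson mean on day(s) ",
         paste(discharge$day[lambda <= 0], collapse = ", "))
  set.seed(seed %% 2147483647)
  data.frame(day = discharge$day,
             unique_detections = stats::rpois(length(lambda), lambda))
}

#' Simulate a nested eDNA survey with known latent structure
#'
#' Runs the three-level model generatively on the log10 scale. For each
#' site and day, a transect mean is drawn about the telemetry regression
#' (at the telemetry site) or about the site baseline (elsewhere) with SD
#' `sigma_telemetry`; each of the transect's point means is drawn about it
#' with SD `sigma_transect`; each replicate observation about its point
#' mean with SD `sigma_point`. All latent values are retained in the truth
#' tables; linear-scale `copies = 10^y` are attached for the qPCR layer.
#'
#' @param config a [study_config()].
#' @param telemetry data frame `day`, `unique_detections` covering every
#'   survey day (see [simulate_telemetry_counts()]).
#' @param seed RNG seed (default derived from `config$rng_seed`).
#' @return list with `survey` (site, date, transect, point, replicate, y,
#'   copies), `truth_transects` (site, date, transect, count, mu_transect),
#'   `truth_points` (transect, point, mu_point), and `sites` (site ids;
#'   the first is the telemetry site).
#' @export
simulate_edna_survey <- function(config, telemetry,
                                 seed = derive_seed(config$rng_seed,
                                                    "survey")) {
  stopifnot(inherits(config, "study_config"))
  days <- config$start_day + seq_len(config$n_days) - 1
  if (!all(days %in% telemetry$day))
    stop("telemetry must cover all survey days")
  set.seed(seed %% 2147483647)
  sites <- paste0("site", seq_len(config$n_sites))
  sites[1] <- "Americus"  # designated telemetry site
  if (config$n_sites >= 2) sites[2] <- "Mascouten"
  if (config$n_sites >= 3) sites[3] <- "FrenchPost"

  cnt <- telemetry$unique_detections[match(days, telemetry$day)]
  tr <- expand.grid(date = days, site = sites, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)[, c("site", "date")]
  if (config$dropout_prob > 0)
    tr <- tr[stats::runif(nrow(tr)) >= config$dropout_prob, , drop = FALSE]
  tr$transect <- paste0(tr$site, "_d", tr$date)
  tr$count <- ifelse(tr$site == sites[1],
                     cnt[match(tr$date, days)], NA_real_)
  tr$mu_transect <- stats::rnorm(
    nrow(tr),
    ifelse(is.na(tr$count), config$site_baseline,
           config$telemetry_intercept + config$telemetry_slope * tr$count),
    config$sigma_telemetry)

  n_pt <- config$points_per_transect
  pts <- tr[rep(seq_len(nrow(tr)), each = n_pt), ]
  pts$point <- rep(seq_len(n_pt), nrow(tr))
  pts$mu_point <- stats::rnorm(nrow(pts), pts$mu_transect,
                               config$sigma_transect)

  n_rep <- config$replicates_per_point
  obs <- pts[rep(seq_len(nrow(pts)), each = n_rep), ]
  obs$replicate <- rep(seq_len(n_rep), nrow(pts))
  obs$y <- stats::rnorm(nrow(obs), obs$mu_point, config$sigma_point)
  obs$copies <- 10^obs$y

  survey <- obs[, c("site", "date", "transect", "point", "replicate",
                    "y", "copies")]
  rownames(survey) <- NULL
  truth_points <- pts[, c("transect", "point", "mu_point")]
  rownames(truth_points) <- NULL
  list(survey = survey,
       truth_transects = tr[, c("site", "date", "transect", "count",
                                "mu_transect")],
       truth_points = truth_points,
       sites = sites)
}

#' Simulate a qPCR plate from known template copies
#'
#' Ct = curve_intercept + curve_slope * log10(copies) + Normal(0,
#' ct_noise_sd) for wells with template; zero-copy wells get the
#' no-amplification marker (`NA` Ct). Selected wells can be displaced by a
#' fixed cycle offset to plant outliers for screening tests.
#'
#' @param true_copies numeric vector of template copies per well (>= 0).
#' @param curve_intercept,curve_slope calibration line (slope < 0).
#' @param ct_noise_sd Ct noise SD (cycles).
#' @param outlier_offset cycles added to the wells in `outlier_indices`.
#' @param outlier_indices integer indices of planted-outlier wells.
#' @param seed RNG seed.
#' @return data frame `well`, `true_copies`, `ct`.
#' @export
simulate_qpcr_plate <- function(true_copies, curve_intercept = 41.61,
                                curve_slope = -3.266, ct_noise_sd = 0,
                                outlier_offset = 0,
                                outlier_indices = integer(0), seed = 1) {
  if (curve_slope >= 0) stop("invalid config: curve_slope must be < 0")
  if (any(true_copies < 0)) stop("true_copies must be >= 0")
  set.seed(seed %% 2147483647)
  n <- length(true_copies)
  ct <- rep(NA_real_, n)
  pos <- true_copies > 0
  ct[pos] <- curve_intercept + curve_slope * log10(true_copies[pos]) +
    stats::rnorm(sum(pos), 0, ct_noise_sd)
  ct[outlier_indices] <- ct[outlier_indices] + outlier_offset
  data.frame(well = sprintf("W%03d", seq_len(n)),
             true_copies = true_copies, ct = ct)
}

#' Simulate pulsed egg drift triggered by rising discharge
#'
#' Days on which the discharge first-difference exceeds
#' `spawn_threshold_rise` trigger a spawning pulse of drifting eggs whose
#' expected density starts at `pulse_density` and decays exponentially with
#' e-folding time `decay_days`. Three bongo-net samples are drawn per day
#' with Poisson counts around expected density x filtered volume.
#'
#' @param discharge data frame `day`, `discharge_m3s`.
#' @param spawn_threshold_rise day-over-day rise (m^3/s) that triggers a
#'   pulse.
#' @param pulse_density peak expected density (eggs/m^3, >= 0).
#' @param decay_days e-folding time of the pulse (days, > 0).
#' @param net_volume filtered volume per net pull (m^3).
#' @param seed RNG seed.
#' @return data frame `day`, `net`, `volume_m3`, `expected_density`,
#'   `egg_count`.
#' @export
simulate_egg_drift <- function(discharge, spawn_threshold_rise = 100,
                               pulse_density = 10000, decay_days = 2,
                               net_volume = 1, seed = 1) {
  if (pulse_density < 0) stop("pulse_density must be >= 0")
  if (decay_days <= 0) stop("decay_days must be > 0")
  set.seed(seed %% 2147483647)
  day <- discharge$day
  rise <- c(0, diff(discharge$discharge_m3s))
  triggers <- day[rise > spawn_threshold_rise]
  dens <- vapply(day, function(d) {
    past <- triggers[triggers <= d]
    if (!length(past)) return(0)
    sum(pulse_density * exp(-(d - past) / decay_days))
  }, numeric(1))
  out <- data.frame(day = rep(day, each = 3), net = rep(1:3, length(day)),
                    volume_m3 = net_volume,
                    expected_density = rep(dens, each = 3))
  out$egg_count <- stats::rpois(nrow(out),
                                out$expected_density * out$volume_m3)
  out
}

#' Generate a complete synthetic study
#'
#' Chains the component generators under one master seed: gage hydrograph,
#' drainage-area-ratio discharge at each site, Poisson telemetry counts at
#' the telemetry site, the nested eDNA survey with retained latent truth,
#' qPCR plates (standards from the 7-point calibration design plus unknown
#' wells for every survey replicate), and pulsed egg drift per site.
#'
#' @param config a [study_config()].
#' @return list with `config`, `sites` (site, drainage_area_ha, is_gaged),
#'   `discharge` (site, date, discharge_m3s), `telemetry` (date,
#'   unique_detections), `survey`, `truth` (parameters and latent tables),
#'   `plate` (standards + unknown wells), `eggs`.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$rng_seed

  hydro <- simulate_hydrograph(config$base_flow, config$peaks,
                               config$flow_noise_sd, config$n_days,
                               seed = derive_seed(seed, "hydrograph"),
                               start_day = config$start_day)
  tel <- simulate_telemetry_counts(hydro, config$glm_intercept,
                                   config$glm_slope,
                                   seed = derive_seed(seed, "telemetry"))
  sv <- simulate_edna_survey(config, tel)

  areas <- c(1134000, 979000, 1013000,
             if (config$n_sites > 3) 900000 + 50000 * seq_len(config$n_sites - 3))
  sites <- data.frame(site = sv$sites,
                      drainage_area_ha = areas[seq_len(config$n_sites)],
                      is_gaged = seq_len(config$n_sites) == 1)
  gage <- data.frame(site = sv$sites[1], date = hydro$day,
                     discharge_m3s = hydro$discharge_m3s)
  q_sites <- discharge_by_site(gage, sites)

  standards <- rep(c(10^(6:1), 0), each = 2)
  plate_std <- simulate_qpcr_plate(standards, config$curve_intercept,
                                   config$curve_slope, config$ct_noise_sd,
                                   seed = derive_seed(seed, "plate"))
  plate_std$sample_type <- "standard"
  plate_std$known_copies <- plate_std$true_copies
  plate_unk <- simulate_qpcr_plate(sv$survey$copies, config$curve_intercept,
                                   config$curve_slope, config$ct_noise_sd,
                                   seed = derive_seed(seed, "plate") + 1)
  plate_unk$well <- sprintf("U%05d", seq_len(nrow(plate_unk)))
  plate_unk$sample_type <- "unknown"
  plate_unk$known_copies <- NA_real_
  plate <- rbind(
    cbind(plate_std[, c("well", "sample_type", "known_copies", "ct")],
          site = NA, date = NA, point = NA, replicate = NA),
    cbind(plate_unk[, c("well", "sample_type", "known_copies", "ct")],
          site = sv$survey$site, date = sv$survey$date,
          point = sv$survey$point, replicate = sv$survey$replicate))
  rownames(plate) <- NULL

  eggs <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    qi <- q_sites[q_sites$site == sites$site[i], ]
    e <- simulate_egg_drift(
      data.frame(day = qi$date, discharge_m3s = qi$discharge_m3s),
      seed = derive_seed(seed, "eggs") + i)
    data.frame(site = sites$site[i], date = e$day, net = e$net,
               egg_count = e$egg_count, volume_m3 = e$volume_m3,
               expected_density = e$expected_density)
  }))
  rownames(eggs) <- NULL

  truth_params <- data.frame(
    parameter = c("telemetry_intercept", "telemetry_slope", "sigma_point",
                  "sigma_transect", "sigma_telemetry", "site_baseline",
                  "glm_intercept", "glm_slope", "curve_intercept",
                  "curve_slope"),
    value = c(config$telemetry_intercept, config$telemetry_slope,
              config$sigma_point, config$sigma_transect,
              config$sigma_telemetry, config$site_baseline,
              config$glm_intercept, config$glm_slope,
              config$curve_intercept, config$curve_slope))

  list(config = config, sites = sites,
       discharge = q_sites,
       telemetry = data.frame(date = tel$day,
                              unique_detections = tel$unique_detections),
       survey = sv$survey,
       truth = list(parameters = truth_params,
                    transects = sv$truth_transects,
                    points = sv$truth_points),
       plate = plate, eggs = eggs)
}
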