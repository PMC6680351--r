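#' Write a simulated study to a directory of pipeline CSV tables
#'
#' Emits the tables the end-to-end pipeline consumes (`plate.csv`,
#' `telemetry.csv`, `gage.csv`, `sites.csv`, `eggs.csv`) plus the ground
#' truth (`truth.csv` with the generating parameters and
#' `truth_transects.csv` with per-site-day latent transect means) and the
#' noise-free `survey.csv`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = sim$config$rng_seed, generator = "ednariver")
  write_table(sim$plate, file.path(dir, "plate.csv"), "plate", meta)
  write_table(sim$telemetry, file.path(dir, "telemetry.csv"), "telemetry",
              meta)
  gaged <- sim$sites$site[sim$sites$is_gaged]
  write_table(sim$discharge[sim$discharge$site %in% gaged, ],
              file.path(dir, "gage.csv"), "discharge", meta)
  write_table(sim$sites, file.path(dir, "sites.csv"), "sites", meta)
  write_table(sim$eggs[, c("site", "date", "net", "egg_count", "volume_m3")],
              file.path(dir, "eggs.csv"), "eggs", meta)
  write_table(sim$survey[, c("site", "date", "transect", "point",
                             "replicate", "copies")],
              file.path(dir, "survey.csv"), "survey", meta)
  write_csv_meta(sim$truth$parameters, file.path(dir, "truth.csv"), meta)
  write_csv_meta(sim$truth$transects, file.path(dir, "truth_transects.csv"),
                 meta)
  invisible(dir)
}

# Deterministic CSV writer with provenance comment header, for output
# tables that have no fixed input schema.
write_csv_meta <- function(df, path, meta = list()) {
  for (cn in names(df))
    if (is.double(df[[cn]])) df[[cn]] <- signif(df[[cn]], 6)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(paste0("# ", nm, ": ", meta[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full eDNA analysis pipeline
#'
#' Chains the analysis stages on a directory of input tables: qPCR
#' calibration and quantification (`curve.json`, `survey.csv`), site
#' discharge by the drainage-area ratio (`discharge_by_site.csv`), egg
#' densities (`densities.csv`), the hierarchical telemetry-eDNA model
#' (`posterior_summary.csv`) and the discharge-count Poisson GLM
#' (`glm.json`). Every output carries the master seed and input checksums
#' in its metadata header; a stage failure writes a `FAILED` marker and
#' halts downstream stages while retaining completed outputs.
#'
#' @param config list with input paths (`plate`, `telemetry`, `gage`,
#'   `sites`, `eggs` -- `plate` may be omitted when `survey` is given
#'   directly), `telemetry_site`, `out_dir`, `seed`, and optional stage
#'   parameters `ct_min`, `grubbs_alpha`, `log_offset`, `mcmc` (list:
#'   n_chains, n_warmup, n_sampling, keep_latent), `glm_link`,
#'   `glm_method`.
#' @return invisible list with the fitted `curve`, `posterior`, `glm`, and
#'   the output directory.
#' @export
run_report <- function(config) {
  cfg <- utils::modifyList(list(
    telemetry_site = "Americus", seed = 1, ct_min = 15, grubbs_alpha = 0.05,
    log_offset = 1, glm_link = "identity", glm_method = "bayes-mcmc",
    mcmc = list(n_chains = 4, n_warmup = 1000, n_sampling = 1000,
                keep_latent = "transect")), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  note <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = logf, append = TRUE)
  fail <- function(stage, e) {
    writeLines(paste0(stage, ": ", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    note("FAILED at ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  }
  inputs <- unlist(cfg[intersect(names(cfg), c("plate", "survey", "telemetry",
                                               "gage", "sites", "eggs"))])
  meta <- list(seed = cfg$seed,
               inputs = paste(names(inputs), unname(tools::md5sum(inputs)),
                              sep = "=", collapse = " "))

  # stage 1: qPCR calibration + quantification
  survey <- curve <- NULL
  tryCatch({
    if (!is.null(cfg$plate)) {
      plate <- read_table(cfg$plate, "plate")
      std <- plate[plate$sample_type == "standard", ]
      curve <- fit_standard_curve(std, cfg$ct_min, cfg$grubbs_alpha)
      jsonlite::write_json(
        c(curve[c("intercept", "slope", "r_squared", "efficiency",
                  "n_used")], list(seed = cfg$seed)),
        file.path(cfg$out_dir, "curve.json"), auto_unbox = TRUE, digits = NA)
      survey <- quantify_samples(plate, curve)$survey
      write_table(survey, file.path(cfg$out_dir, "survey.csv"), "survey",
                  c(meta, list(ct_min = cfg$ct_min,
                               grubbs_alpha = cfg$grubbs_alpha)))
    } else {
      survey <- read_table(cfg$survey, "survey")
    }
    note("qpcr stage complete: ", nrow(survey), " survey rows")
  }, error = function(e) fail("qpcr", e))

  # stage 2: discharge transfer
  q_sites <- NULL
  tryCatch({
    q_sites <- discharge_by_site(read_table(cfg$gage, "discharge"),
                                 read_table(cfg$sites, "sites"))
    write_table(q_sites, file.path(cfg$out_dir, "discharge_by_site.csv"),
                "discharge", meta)
    note("hydro stage complete")
  }, error = function(e) fail("hydro", e))

  # stage 3: egg densities
  tryCatch({
    dens <- egg_density_table(read_table(cfg$eggs, "eggs"))
    write_csv_meta(dens, file.path(cfg$out_dir, "densities.csv"), meta)
    note("eggs stage complete")
  }, error = function(e) fail("eggs", e))

  # stage 4: hierarchical telemetry-eDNA model
  post <- NULL
  tryCatch({
    tel <- read_table(cfg$telemetry, "telemetry")
    hd <- prepare_hier_data(survey, tel, cfg$telemetry_site, cfg$log_offset)
    post <- fit_hierarchical(hd, n_chains = cfg$mcmc$n_chains,
                             n_warmup = cfg$mcmc$n_warmup,
                             n_sampling = cfg$mcmc$n_sampling,
                             seed = cfg$seed,
                             keep_latent = cfg$mcmc$keep_latent)
    write_csv_meta(post$summary,
                   file.path(cfg$out_dir, "posterior_summary.csv"),
                   c(meta, list(log_offset = cfg$log_offset)))
    note("fit stage complete; slope posterior mean ",
         signif(post$summary$mean[post$summary$parameter ==
                                    "telemetry_slope"], 4))
  }, error = function(e) fail("fit", e))

  # stage 5: discharge-count GLM
  glm_fit <- NULL
  tryCatch({
    tel <- read_table(cfg$telemetry, "telemetry")
    q_tel <- q_sites[q_sites$site == cfg$telemetry_site, ]
    glm_fit <- fit_poisson_glm(tel, q_tel, link = cfg$glm_link,
                               method = cfg$glm_method, seed = cfg$seed)
    jsonlite::write_json(
      c(glm_fit[c("intercept", "slope", "interval_95", "link", "method",
                  "n_days")], list(seed = cfg$seed)),
      file.path(cfg$out_dir, "glm.json"), auto_unbox = TRUE, digits = NA)
    note("glm stage complete; slope ", signif(glm_fit$slope, 4))
  }, error = function(e) fail("glm", e))

  invisible(list(curve = curve, posterior = post, glm = glm_fit,
                 out_dir = cfg$out_dir))
}
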