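# ednariver

Quantitative environmental DNA (eDNA) surveillance of river fish movement
and spawning, built around the nested survey design used for invasive
bigheaded carps (*Hypophthalmichthys* spp.): daily cross-river transects of
surface-water samples analysed by qPCR in duplicate, acoustic-telemetry
counts of tagged fish at a receiver site, gage discharge transferred to
ungaged sites, and drifting-egg densities from bongo-net pulls.

The scientific core is a three-level hierarchical Bayesian model linking
replicate-level log10 copy numbers to fish movement. With observation *i*
in point *p* in transect *t* (one transect per site per day) and *c_t* the
day's count of unique telemetry detections:

```
y_i   ~ Normal(mu_p,               sigma_point^2)
mu_p  ~ Normal(mu_t,               sigma_transect^2)
mu_t  ~ Normal(beta0 + beta1 c_t,  sigma_telemetry^2)   (telemetry site)
```

`beta1` — log10 copies per detected fish — measures whether moving fish
leave measurably more DNA. Weakly informative conjugate priors make every
full conditional closed-form, and the model is fitted by a Gibbs sampler
with split R-hat diagnostics and 80%/95% equal-tailed credible intervals.

Around that core the package provides:

* `fit_standard_curve()` / `ct_to_copies()` — qPCR calibration with the
  strict Ct > 15 inclusion rule and iterative Grubbs outlier screening of
  the regression residuals (`grubbs_outlier()`), plus amplification
  efficiency QC;
* `transfer_discharge()` / `discharge_by_site()` — drainage-area-ratio
  streamflow transfer to ungaged sites;
* `egg_density()` — per-net and event-mean drifting-egg densities;
* `fit_poisson_glm()` — identity-link Poisson regression of daily
  detection counts on discharge (Bayesian by default, Wald MLE optional);
* `simulate_study()` and friends — a synthetic-data generator that runs
  the whole design forward from known parameters (bimodal flood
  hydrograph, Poisson telemetry counts, nested copy numbers, qPCR plates,
  pulsed egg drift) with full latent ground truth;
* `run_report()` — the end-to-end pipeline from input CSV tables to fitted
  objects, with deterministic, seed-stamped outputs.

See `vignettes/edna-telemetry-model.Rmd` for the model, its assumptions,
and every numerical choice.

## Worked example

```r
library(ednariver)

# 1. Calibrate a standard curve; one well is corrupted by +8 cycles.
std <- data.frame(known_copies = rep(10^(1:6), 2),
                  ct = 41.61 - 3.266 * log10(rep(10^(1:6), 2)))
std$ct[3] <- std$ct[3] + 8
curve <- fit_standard_curve(std)
print(curve)
#> qPCR standard curve: Ct = 41.61 + -3.266 * log10(copies)
#>   r^2 = 1  efficiency = 1.024  n_used = 11
#>   excluded wells:
#>  .row known_copies     ct         reason
#>     3         1000 39.812 grubbs-outlier

# 2. Simulate a study (truth: beta1 = 1) and fit the hierarchical model.
sim <- simulate_study(study_config(n_days = 15, rng_seed = 7))
hd  <- prepare_hier_data(sim$survey, sim$telemetry,
                         telemetry_site = "Americus")
fit <- fit_hierarchical(hd, n_chains = 4, n_warmup = 500, n_sampling = 500,
                        seed = 7, keep_latent = "none")
print(fit)
#> Hierarchical eDNA model posterior: 4 chains x 500 sampling iterations ( 500 warmup )
#>            parameter   mean median    lo80   hi80    lo95   hi95   rhat
#>  telemetry_intercept 1.9147 1.9147  1.6346 2.1908  1.4837 2.3430 1.0014
#>      telemetry_slope 1.0534 1.0535  0.9644 1.1439  0.9103 1.2029 1.0000
#>          sigma_point 0.5008 0.5006  0.4851 0.5171  0.4767 0.5275 1.0284
#>       sigma_transect 0.2563 0.2554  0.2278 0.2879  0.2087 0.3028 1.0530
#>      sigma_telemetry 0.5345 0.5159  0.4018 0.6897  0.3548 0.8123 0.9987
#>         m_FrenchPost 1.8422 1.8264 -1.3245 4.9255 -2.9695 6.5566 0.9996
#>          m_Mascouten 1.9971 2.0994 -1.1303 5.0274 -2.9698 6.7394 0.9995

# 3. Movement vs discharge at the receiver site.
glm_fit <- fit_poisson_glm(sim$telemetry,
                           subset(sim$discharge, site == "Americus"),
                           seed = 7)
print(glm_fit)
#> Poisson GLM (identity link, bayes-mcmc), 15 days
#>   slope     0.005182 [0.00152, 0.009057]
#>   intercept -0.5058
```

The calibration screen found the planted bad well and recovered the
generating line exactly. The slope posterior mean 1.05 with 95% interval
(0.91, 1.20) recovers the generating value beta1 = 1 — each additional
detected fish raises transect-level eDNA by about one order of magnitude in
this simulation — and the GLM slope 0.0052 fish/(m³/s) with an interval
excluding zero recovers the generating weak positive trend (0.004). The
wide `m_*` intervals are by design: site levels for transects without
telemetry are deliberately weak anchors.

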