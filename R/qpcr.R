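#' Fit a qPCR standard curve with inclusion and outlier rules
#'
#' Fits the calibration line Ct = a + b * log10(copies) by ordinary least
#' squares after applying, in order: (i) exclusion of the zero-copy standard
#' and of wells that failed to amplify, (ii) exclusion of standards with
#' Ct <= `ct_min` (early crossings indicate saturation or artefacts; the
#' inclusion rule is strict: only Ct > `ct_min` wells are used), and
#' (iii) iterative single-point Grubbs screening of the regression residuals:
#' at each round the fit is recomputed, [grubbs_outlier()] is applied to the
#' residuals, and the single flagged standard (if any) is dropped, until no
#' outlier remains at level `grubbs_alpha`.
#'
#' @param standards data frame with columns `known_copies` (copies per
#'   reaction, >= 0) and `ct` (cycle threshold; `NA` marks a well with no
#'   amplification).
#' @param ct_min cycle-threshold inclusion bound; standards with
#'   Ct <= `ct_min` are excluded (default 15 cycles).
#' @param grubbs_alpha significance level for the residual Grubbs screen.
#' @return an object of class `standard_curve`: a list with `intercept` (a,
#'   cycles), `slope` (b, cycles per log10 copy), `r_squared`, `efficiency`
#'   (from [amplification_efficiency()], `NA` if the slope is non-negative),
#'   `n_used`, `excluded` (data frame of dropped wells with a `reason` among
#'   `"zero-standard"`, `"no-amplification"`, `"below-ct-threshold"`,
#'   `"grubbs-outlier"`), and `slope_nonnegative` (diagnostic flag; such a
#'   curve cannot be inverted by [ct_to_copies()]).
#' @examples
#' std <- data.frame(known_copies = 10^(1:6),
#'                   ct = 41.61 - 3.266 * (1:6))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, ct_min = 15, grubbs_alpha = 0.05) {
  stopifnot(is.data.frame(standards),
            all(c("known_copies", "ct") %in% names(standards)))
  if (any(standards$known_copies < 0, na.rm = TRUE))
    stop("known_copies must be >= 0")

  st <- standards[, c("known_copies", "ct")]
  st$.row <- seq_len(nrow(st))
  reason <- rep(NA_character_, nrow(st))
  reason[st$known_copies == 0] <- "zero-standard"
  reason[is.na(reason) & is.na(st$ct)] <- "no-amplification"
  reason[is.na(reason) & st$ct <= ct_min] <- "below-ct-threshold"

  repeat {
    use <- is.na(reason)
    if (sum(use) < 3)
      stop("insufficient standards: fewer than 3 usable points after exclusions")
    fit <- stats::lm(ct ~ log10(known_copies), data = st[use, ])
    res <- stats::residuals(fit)
    # an exact fit leaves only rounding noise; nothing there to screen
    if (stats::sd(res) < 1e-8 * max(stats::sd(st$ct[use]), 1)) break
    out <- grubbs_outlier(res, alpha = grubbs_alpha)
    if (is.na(out)) break
    reason[which(use)[out]] <- "grubbs-outlier"
  }

  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  # noiseless standards give an exact fit; summary.lm warns about it
  r2 <- suppressWarnings(summary(fit)$r.squared)
  excluded <- st[!is.na(reason), ]
  excluded$reason <- reason[!is.na(reason)]
  structure(list(
    intercept = a,
    slope = b,
    r_squared = r2,
    efficiency = if (b < 0) amplification_efficiency(b) else NA_real_,
    n_used = sum(is.na(reason)),
    excluded = excluded[, c(".row", "known_copies", "ct", "reason")],
    slope_nonnegative = b >= 0
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Ct =", format(x$intercept, digits = 6), "+",
      format(x$slope, digits = 6), "* log10(copies)\n")
  cat("  r^2 =", format(x$r_squared, digits = 4),
      " efficiency =", format(x$efficiency, digits = 4),
      " n_used =", x$n_used, "\n")
  if (nrow(x$excluded)) {
    cat("  excluded wells:\n")
    print(x$excluded, row.names = FALSE)
  }
  if (x$slope_nonnegative)
    cat("  WARNING: non-negative slope; curve is not invertible\n")
  invisible(x)
}

#' Back-calculate copy numbers from Ct values
#'
#' Inverts the standard curve: copies = 10^((Ct - a) / b). Wells with no
#' amplification (`NA` Ct) are assigned 0 copies.
#'
#' @param ct numeric vector of cycle thresholds; `NA` = no amplification.
#' @param curve a `standard_curve`, or any list with `intercept` and `slope`.
#' @return numeric vector of copies per reaction.
#' @examples
#' curve <- list(intercept = 41.61, slope = -3.266)
#' ct_to_copies(41.61, curve)   # 1 copy
#' ct_to_copies(NA, curve)      # 0 copies
#' @export
ct_to_copies <- function(ct, curve) {
  if (!is.numeric(curve$slope) || !(curve$slope < 0))
    stop("invalid standard curve: slope must be negative")
  copies <- 10^((ct - curve$intercept) / curve$slope)
  copies[is.na(ct)] <- 0
  copies
}

#' qPCR amplification efficiency from the curve slope
#'
#' E = 10^(-1/b) - 1; an efficiency of 1 corresponds to perfect per-cycle
#' doubling of template (slope -1/log10(2) ~ -3.3219).
#'
#' @param slope curve slope b (cycles per log10 copy), must be negative.
#' @return efficiency, unitless.
#' @export
amplification_efficiency <- function(slope) {
  if (!is.numeric(slope) || is.na(slope) || slope >= 0)
    stop("amplification efficiency requires a negative slope")
  10^(-1 / slope) - 1
}

#' Quantify unknown wells on a qPCR plate
#'
#' Applies [ct_to_copies()] to every `unknown` well and assembles the nested
#' survey table. Duplicate reactions of the same water sample are kept as
#' separate replicate rows -- they are the replicate-level responses of the
#' hierarchical model and must never be averaged upstream of it. No-template
#' and field controls are reported separately; any control that amplifies
#' raises a contamination flag (the run continues).
#'
#' @param plate data frame with columns `well`, `sample_type` (one of
#'   `standard`, `unknown`, `ntc`, `field_control`), `known_copies`, `site`,
#'   `date`, `point`, `replicate`, `ct` (`NA` = no amplification).
#' @param curve a fitted `standard_curve` (slope < 0).
#' @return list with `survey` (data frame: site, date, transect, point,
#'   replicate, copies -- one transect per site-date, labelled
#'   `<site>_d<date>`), `controls` (control wells with copies), and
#'   `contamination` (logical).
#' @export
quantify_samples <- function(plate, curve) {
  need <- c("well", "sample_type", "site", "date", "point", "replicate", "ct")
  stopifnot(is.data.frame(plate), all(need %in% names(plate)))
  unk <- plate[plate$sample_type == "unknown", ]
  key_cols <- c("site", "date", "point", "replicate")
  bad <- apply(is.na(unk[key_cols]) | unk[key_cols] == "", 1, any)
  if (any(bad))
    stop("unknown well(s) without a (site, date, point, replicate) key: ",
         paste(unk$well[bad], collapse = ", "))

  ctl <- plate[plate$sample_type %in% c("ntc", "field_control"), ]
  controls <- data.frame(well = ctl$well, sample_type = ctl$sample_type,
                         ct = ctl$ct, copies = ct_to_copies(ctl$ct, curve))
  contamination <- any(!is.na(ctl$ct))
  if (contamination)
    warning("control well(s) amplified: ",
            paste(ctl$well[!is.na(ctl$ct)], collapse = ", "))

  survey <- data.frame(
    site = unk$site, date = unk$date,
    transect = if (nrow(unk)) paste0(unk$site, "_d", unk$date)
               else character(0),
    point = unk$point, replicate = unk$replicate,
    copies = ct_to_copies(unk$ct, curve)
  )
  list(survey = survey, controls = controls, contamination = contamination)
}
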