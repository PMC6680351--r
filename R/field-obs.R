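#' Egg density from bongo-net samples of one site-date event
#'
#' Per-net density is egg count divided by filtered water volume; the event
#' value is the unweighted arithmetic mean over the nets that were pulled
#' (normally three, but a single-net event is accepted and flagged). The
#' pooled ratio total-eggs / total-volume is also reported for comparison;
#' it equals the mean of per-net densities only when volumes are equal.
#'
#' @param egg_count integer vector of eggs counted per net (>= 0).
#' @param volume numeric vector of filtered volumes per net (m^3, > 0).
#' @return list with `density` (mean eggs/m^3), `per_net` (eggs/m^3 per
#'   net), `pooled` (total eggs / total volume), `n_nets`.
#' @examples
#' egg_density(c(10, 20, 30), c(1, 1, 1))$density  # 20 eggs/m^3
#' @export
egg_density <- function(egg_count, volume) {
  if (length(egg_count) < 1 || length(egg_count) != length(volume))
    stop("need >= 1 net with matching counts and volumes")
  if (any(volume <= 0)) stop("invalid sample: filtered volume must be > 0")
  if (any(egg_count < 0)) stop("invalid sample: egg counts must be >= 0")
  per_net <- egg_count / volume
  list(density = mean(per_net), per_net = per_net,
       pooled = sum(egg_count) / sum(volume), n_nets = length(egg_count))
}

#' Egg densities for every site-date event in an egg-sample table
#'
#' @param eggs data frame with columns `site`, `date`, `net`, `egg_count`,
#'   `volume_m3`.
#' @return data frame with one row per (site, date): mean and pooled density
#'   and the number of nets.
#' @export
egg_density_table <- function(eggs) {
  stopifnot(all(c("site", "date", "egg_count", "volume_m3") %in% names(eggs)))
  sp <- split(eggs, list(eggs$site, eggs$date), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    d <- egg_density(g$egg_count, g$volume_m3)
    data.frame(site = g$site[1], date = g$date[1],
               density = d$density, pooled_density = d$pooled,
               n_nets = d$n_nets)
  }))
  rownames(out) <- NULL
  out[order(out$site, out$date), ]
}

#' Transfer gaged discharge to an ungaged site by the drainage-area ratio
#'
#' Assumes the ratio of discharges at two locations equals the ratio of
#' their drainage areas: Q_target = Q_gage * A_target / A_gage. The transfer
#' is linear in discharge and transitive across sites.
#'
#' @param q_gage discharge at the gaged site (m^3/s, >= 0); vectorized.
#' @param area_gage,area_target drainage areas (same units, > 0; the study
#'   reach uses hectares).
#' @return discharge at the target site (m^3/s).
#' @examples
#' # Logansport gage (979,000 ha) to Americus (1,134,000 ha)
#' transfer_discharge(100, 979000, 1134000)
#' @export
transfer_discharge <- function(q_gage, area_gage, area_target) {
  if (any(area_gage <= 0) || any(area_target <= 0))
    stop("drainage areas must be > 0")
  if (any(q_gage < 0, na.rm = TRUE)) stop("discharge must be >= 0")
  q_gage * area_target / area_gage
}

#' Site-level discharge series from a gage record
#'
#' Gaged sites keep their own record unadjusted; ungaged sites receive the
#' gage record scaled by [transfer_discharge()].
#'
#' @param gage data frame `site`, `date`, `discharge_m3s` for the gaged
#'   site(s).
#' @param sites data frame `site`, `drainage_area_ha`, `is_gaged`.
#' @param gage_site site id of the reference gage (default: the first gaged
#'   site in `sites`).
#' @return data frame `site`, `date`, `discharge_m3s` covering every site.
#' @export
discharge_by_site <- function(gage, sites, gage_site = NULL) {
  stopifnot(all(c("site", "date", "discharge_m3s") %in% names(gage)),
            all(c("site", "drainage_area_ha", "is_gaged") %in% names(sites)))
  if (is.null(gage_site)) gage_site <- sites$site[sites$is_gaged][1]
  if (is.na(gage_site)) stop("no gaged site available")
  ref <- gage[gage$site == gage_site, ]
  if (!nrow(ref)) stop("no gage record for site ", gage_site)
  a_gage <- sites$drainage_area_ha[sites$site == gage_site]
  out <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites$site[i]
    own <- gage[gage$site == s, ]
    if (sites$is_gaged[i] && nrow(own)) return(own)
    data.frame(site = s, date = ref$date,
               discharge_m3s = transfer_discharge(
                 ref$discharge_m3s, a_gage, sites$drainage_area_ha[i]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$site, out$date), ]
}

#' Drainage areas of the study-reach sites
#'
#' Published drainage areas (hectares) for the Wabash River sites used
#' throughout the examples: the Logansport gage and the ungaged French Post
#' and Americus transects, plus the separately gaged Mascouten site
#' (Lafayette gage).
#' @return named numeric vector of drainage areas in hectares.
#' @export
study_drainage_areas <- function() {
  c(Logansport = 979000, FrenchPost = 1013000, Americus = 1134000)
}
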