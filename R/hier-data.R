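#' Assemble nested eDNA observations for the hierarchical model
#'
#' Builds the response and nesting indices for the three-level model:
#' replicate-level log10 copy numbers within points, points within transects
#' (one transect per site-date), with the daily count of unique telemetry
#' detections as a transect-level covariate at the telemetry site only.
#' Copy numbers are transformed as y = log10(copies + log_offset); the
#' offset accommodates non-detects (0 copies) and is recorded in the result
#' so downstream reports can state it.
#'
#' @param survey data frame with columns `site`, `date`, `transect`,
#'   `point`, `replicate`, `copies` (copies per reaction, >= 0).
#' @param telemetry data frame with columns `date`, `unique_detections`
#'   (integer >= 0).
#' @param telemetry_site site id whose transects carry the covariate.
#' @param log_offset copies added before the log10 transform (default 1).
#'   Must be > 0 unless every observation has copies > 0.
#' @return object of class `hier_data`: list with `y`, `point` (observation
#'   -> point index), `transect_of_point`, `site_of_transect`, `count`
#'   (per-transect covariate, `NA` off the telemetry site), label tables
#'   (`points`, `transects`, `sites`) and `log_offset`.
#' @export
prepare_hier_data <- function(survey, telemetry, telemetry_site,
                              log_offset = 1) {
  need <- c("site", "date", "transect", "point", "replicate", "copies")
  stopifnot(is.data.frame(survey), all(need %in% names(survey)))
  if (any(survey$copies < 0)) stop("copies must be >= 0")
  if (log_offset < 0) stop("log_offset must be >= 0")
  if (log_offset == 0 && any(survey$copies == 0))
    stop("undefined transform: copies = 0 with log_offset = 0")

  y <- log10(survey$copies + log_offset)
  # canonical (sorted) point and transect indexing, so the fit does not
  # depend on observation order
  point_key <- paste(survey$transect, survey$point, sep = ":")
  points <- unique(data.frame(key = point_key, transect = survey$transect,
                              stringsAsFactors = FALSE))
  points <- points[order(points$key), ]
  transects <- unique(data.frame(transect = survey$transect,
                                 site = survey$site, date = survey$date,
                                 stringsAsFactors = FALSE))
  transects <- transects[order(transects$transect), ]
  if (anyDuplicated(transects$transect))
    stop("a transect id maps to more than one (site, date)")

  point <- match(point_key, points$key)
  transect_of_point <- match(points$transect, transects$transect)
  site_of_transect <- match(transects$site, unique(transects$site))

  count <- rep(NA_real_, nrow(transects))
  at_tel <- transects$site == telemetry_site
  if (any(at_tel)) {
    m <- match(transects$date[at_tel], telemetry$date)
    count[at_tel] <- telemetry$unique_detections[m]
  }
  if (any(at_tel & is.na(count)))
    stop("telemetry counts missing for telemetry-site date(s): ",
         paste(unique(transects$date[at_tel & is.na(count)]), collapse = ", "))

  structure(list(
    y = y, point = point,
    transect_of_point = transect_of_point,
    site_of_transect = site_of_transect,
    count = count,
    points = points, transects = transects,
    sites = unique(transects$site),
    telemetry_site = telemetry_site,
    log_offset = log_offset
  ), class = "hier_data")
}
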