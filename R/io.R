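#' Table schemas used by the pipeline
#'
#' Named list mapping a schema id to its required columns, column types and
#' (optionally) the duplicate-key columns. All tables are UTF-8 CSV with a
#' header row; lines starting with `#` carry provenance metadata and are
#' ignored on read.
#'
#' @return named list of schema definitions.
#' @export
table_schemas <- function() {
  list(
    survey = list(
      cols = c(site = "character", date = "integer", transect = "character",
               point = "integer", replicate = "integer", copies = "numeric"),
      key = c("site", "date", "point", "replicate")),
    plate = list(
      cols = c(well = "character", sample_type = "character",
               known_copies = "numeric", site = "character",
               date = "integer", point = "integer", replicate = "integer",
               ct = "numeric"),
      key = "well"),
    telemetry = list(
      cols = c(date = "integer", unique_detections = "integer"),
      key = "date"),
    discharge = list(
      cols = c(site = "character", date = "integer",
               discharge_m3s = "numeric"),
      key = c("site", "date")),
    sites = list(
      cols = c(site = "character", drainage_area_ha = "numeric",
               is_gaged = "logical"),
      key = "site"),
    eggs = list(
      cols = c(site = "character", date = "integer", net = "integer",
               egg_count = "integer", volume_m3 = "numeric"),
      key = c("site", "date", "net"))
  )
}

#' Read and validate a pipeline CSV table
#'
#' @param path CSV file path.
#' @param schema schema id, one of `names(table_schemas())`.
#' @return typed data frame (zero rows are fine). Errors name the offending
#'   column or rows: a missing column, an unparseable cell, or a duplicated
#'   key.
#' @export
read_table <- function(path, schema) {
  sc <- table_schemas()[[schema]]
  if (is.null(sc)) stop("unknown schema: ", schema)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = NA)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing))
    stop("table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, names(sc$cols), drop = FALSE]
  for (cn in names(sc$cols)) {
    target <- sc$cols[[cn]]
    conv <- switch(target, character = as.character, integer = as.integer,
                   numeric = as.numeric, logical = as.logical)
    suppressWarnings(val <- conv(df[[cn]]))
    bad <- which(is.na(val) & !is.na(df[[cn]]) & df[[cn]] != "")
    if (length(bad))
      stop("table ", path, ", column ", cn, ": unparseable value in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    df[[cn]] <- val
  }
  if (!is.null(sc$key) && nrow(df)) {
    keys <- do.call(paste, c(df[sc$key], sep = "\r"))
    dup <- which(duplicated(keys) | duplicated(keys, fromLast = TRUE))
    if (length(dup))
      stop("table ", path, ": duplicated key (", paste(sc$key, collapse = ","),
           ") in rows ", paste(dup, collapse = ", "))
  }
  df
}

#' Write a pipeline CSV table deterministically
#'
#' Rows are sorted by the schema key, floating-point values are written
#' with 6 significant digits, and provenance metadata (seed, parameters) is
#' recorded as leading `#` comment lines so a rerun with the same inputs is
#' byte-identical.
#'
#' @param df data frame conforming to the schema.
#' @param path output path.
#' @param schema schema id.
#' @param meta named list written as `# name: value` header lines.
#' @return the path, invisibly.
#' @export
write_table <- function(df, path, schema, meta = list()) {
  sc <- table_schemas()[[schema]]
  if (is.null(sc)) stop("unknown schema: ", schema)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing))
    stop("data frame is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, names(sc$cols), drop = FALSE]
  if (!is.null(sc$key) && nrow(df))
    df <- df[do.call(order, df[sc$key]), , drop = FALSE]
  for (cn in names(df))
    if (is.double(df[[cn]])) df[[cn]] <- signif(df[[cn]], 6)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(paste0("# ", nm, ": ", meta[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Julian day of a calendar date (day of year)
#'
#' @param date a `Date` or string coercible to one.
#' @return integer day of year (1-366).
#' @examples
#' julian_day("2013-06-03")  # 154
#' @export
julian_day <- function(date) {
  as.POSIXlt(as.Date(date))$yday + 1L
}
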