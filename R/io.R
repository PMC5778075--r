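# Plain-text interchange: long-format CSV for gridded fields and index
# tables, JSON for models and verification reports.  Every file written by
# the pipeline carries provenance metadata (package version, seed, config
# digest).

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config)), collapse = ""), f)
  unname(tools::md5sum(f))
}

provenance <- function(config = NULL, seed = NULL) {
  list(package = "csiforecast",
       version = as.character(utils::packageVersion("csiforecast")),
       config_digest = if (is.null(config)) NA_character_ else config_digest(config),
       seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Write / read national yield series as CSV
#'
#' @param yields data frame with columns country, year, yield.
#' @param path CSV file path.
#' @return `read_yields_csv` returns the data frame.
#' @export
write_yields_csv <- function(yields, path) {
  utils::write.csv(yields[, c("country", "year", "yield")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_yields_csv
#' @export
read_yields_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Monthly climate fields as a long data frame
#'
#' @param climate a `csi_climate`.
#' @return data frame with year, month, lat, lon, tmean, precip.
#' @export
climate_monthly_df <- function(climate) {
  ny <- dim(climate$tmean)[1]
  nc <- dim(climate$tmean)[3]
  grid <- expand.grid(year = climate$years, month = 1:12,
                      cell = seq_len(nc), KEEP.OUT.ATTRS = FALSE)
  data.frame(year = grid$year, month = grid$month,
             lat = climate$coords$lat[grid$cell],
             lon = climate$coords$lon[grid$cell],
             tmean = as.vector(climate$tmean),
             precip = as.vector(climate$precip))
}

#' Per-country index series as a tidy table
#'
#' @param calibration a `csi_calibration`.
#' @return data frame with country, year, variable, value, timescale,
#'   ending_month.
#' @export
index_table <- function(calibration) {
  rows <- lapply(calibration$records, function(r) {
    if (is.null(r$model)) return(NULL)
    rbind(
      data.frame(country = r$country, year = calibration$years,
                 variable = "hdd_std", value = r$hdd_series,
                 timescale = NA_integer_, ending_month = NA_integer_),
      data.frame(country = r$country, year = calibration$years,
                 variable = "spei_opt", value = r$spei_series,
                 timescale = r$model$k, ending_month = r$model$ending_month),
      data.frame(country = r$country, year = calibration$years,
                 variable = "csi", value = r$csi_obs,
                 timescale = r$model$k, ending_month = r$model$ending_month)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialise calibrated CSI models to JSON
#'
#' @param calibration a `csi_calibration`.
#' @param path output JSON path.
#' @param config optional generator/pipeline config recorded as provenance.
#' @export
write_models_json <- function(calibration, path, config = NULL) {
  models <- lapply(calibration$records, function(r) {
    if (is.null(r$model)) {
      list(country = r$country, included = FALSE, reason = r$reason)
    } else {
      list(country = r$country, included = r$included,
           reason = r$reason, a = r$model$a, b = r$model$b,
           ridge_lambda = r$model$ridge_lambda, timescale = r$model$k,
           ending_month = r$model$ending_month, q2 = r$model$q2,
           p_value = r$p_value, threshold = r$threshold)
    }
  })
  jsonlite::write_json(
    list(provenance = provenance(config, calibration$seed), models = models),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialise a verification report to JSON
#'
#' @param verification a `csi_verification`.
#' @param path output JSON path.
#' @param config optional config recorded as provenance.
#' @export
write_verification_json <- function(verification, path, config = NULL) {
  reports <- lapply(verification$reports, function(rep) {
    list(experiment = rep$experiment,
         correlations = rep$correlations,
         reliability = list(bins = rep$reliability$bins,
                            slope = rep$reliability$slope,
                            slope_ci = rep$reliability$slope_ci,
                            climatology = rep$reliability$climatology),
         roc = list(points = rep$roc$points, area = rep$roc$area,
                    rocss = rep$roc$rocss, rocss_ci = rep$roc$rocss_ci),
         ets = rep$ets)
  })
  jsonlite::write_json(
    list(provenance = provenance(config, verification$seed),
         reports = reports),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
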