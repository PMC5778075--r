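# Synthetic agro-climate testbed: gridded weather, crop masks, national
# yields with known climate sensitivity, and skill-tunable ensemble
# re-forecasts.  Every downstream stage of the CSI pipeline can be exercised
# against the ground truth these generators record.

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_OF_DOY <- rep(1:12, DAYS_IN_MONTH)
JJA_DOYS <- which(MONTH_OF_DOY %in% 6:8)

#' Configuration for the synthetic agro-climate testbed
#'
#' Bundles every tunable of the synthetic generators: grid and period sizes,
#' the spatial/temporal anomaly structure of the weather model, the
#' yield-signal coefficients, and the knobs that control ensemble re-forecast
#' quality (skill, bias, dispersion).
#'
#' @param n_years number of simulated years (>= 20, mirroring the
#'   at-least-20-years inclusion rule for national yield series; default 30,
#'   the length of a 1981-2010-style study period).
#' @param n_lat,n_lon grid dimensions (1-degree cells).
#' @param n_countries number of contiguous country blocks the grid is split
#'   into.
#' @param n_members ensemble size of the re-forecasts (default 10).
#' @param skill_rho correlation in [0, 1] between each forecast member's
#'   anomaly signal and the observed anomaly; 0 emulates a climatological
#'   land-surface initialisation (CLIM), values near 1 a realistic one (INIT).
#' @param bias_temp additive temperature bias of the raw forecasts (degrees C).
#' @param bias_precip additive monthly precipitation bias (mm).
#' @param dispersion multiplicative inflation of forecast anomaly spread.
#' @param yield_coeffs named numeric, coefficients of the standardised yield
#'   signal on (SPEI*, HDD*); heat stress hurts, so the HDD coefficient is
#'   negative by default.
#' @param trend_coeffs linear and quadratic coefficients of the decadal
#'   log-yield trend (per year, per year^2, on centred year).
#' @param noise_sd standard deviation of the non-climatic residual on the
#'   standardised-signal scale.
#' @param signal_scale factor converting the standardised climate-plus-noise
#'   signal to log-yield units (default 0.15, i.e. interannual yield swings
#'   of roughly 10-20%); cancels out of every standardised quantity.
#' @param spei_k,spei_month SPEI aggregation window (months) and ending month
#'   that actually drive the synthetic yield signal; the calibration has to
#'   rediscover them.
#' @param t_thr heat-degree-day temperature threshold, degrees C.
#' @param anomaly_sd_temp,anomaly_sd_precip standard deviation of the
#'   spatially correlated monthly anomaly fields (degrees C, mm).
#' @param anomaly_cor correlation between temperature and precipitation
#'   monthly anomalies (negative: hot summers tend to be dry).
#' @param corr_length e-folding distance (grid degrees) of the exponential
#'   spatial correlation of anomaly fields.
#' @param noise_sd_tmax,noise_sd_tmean,noise_sd_precip cell-level white noise
#'   on daily maximum temperature, monthly mean temperature and monthly
#'   precipitation.
#' @param lat0,lon0 coordinates of the grid's first cell.
#' @param seed integer RNG seed; all generators are bit-reproducible given the
#'   configuration.
#'
#' @return a list of class `csi_config`.
#' @export
synth_config <- function(n_years = 30, n_lat = 6, n_lon = 6, n_countries = 4,
                         n_members = 10, skill_rho = 0.8,
                         bias_temp = 2, bias_precip = 10, dispersion = 1.5,
                         yield_coeffs = c(spei = 0.4, hdd = -0.6),
                         trend_coeffs = c(linear = 0.015, quadratic = -2e-4),
                         noise_sd = 0.5, signal_scale = 0.15,
                         spei_k = 2, spei_month = 7,
                         t_thr = 30,
                         anomaly_sd_temp = 1.2, anomaly_sd_precip = 18,
                         anomaly_cor = -0.3, corr_length = 3,
                         noise_sd_tmax = 2.5, noise_sd_tmean = 0.4,
                         noise_sd_precip = 8,
                         lat0 = 44, lon0 = 5, seed = 1L) {
  if (n_years < 20) {
    stop("configuration error: n_years must be >= 20")
  }
  counts <- c(n_lat = n_lat, n_lon = n_lon, n_countries = n_countries,
              n_members = n_members)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("configuration error: grid, country and member counts must be positive integers")
  }
  if (!is.finite(skill_rho) || skill_rho < 0 || skill_rho > 1) {
    stop("configuration error: skill_rho must lie in [0, 1]")
  }
  if (abs(anomaly_cor) > 1) stop("configuration error: anomaly_cor must lie in [-1, 1]")
  if (corr_length <= 0) stop("configuration error: corr_length must be positive")
  if (length(yield_coeffs) != 2) stop("configuration error: yield_coeffs must have 2 elements")
  structure(list(
    n_years = as.integer(n_years), n_lat = as.integer(n_lat),
    n_lon = as.integer(n_lon), n_countries = as.integer(n_countries),
    n_members = as.integer(n_members), skill_rho = skill_rho,
    bias_temp = bias_temp, bias_precip = bias_precip, dispersion = dispersion,
    yield_coeffs = stats::setNames(as.numeric(yield_coeffs), c("spei", "hdd")),
    trend_coeffs = stats::setNames(as.numeric(trend_coeffs), c("linear", "quadratic")),
    noise_sd = noise_sd, signal_scale = signal_scale,
    spei_k = as.integer(spei_k),
    spei_month = as.integer(spei_month), t_thr = t_thr,
    anomaly_sd_temp = anomaly_sd_temp, anomaly_sd_precip = anomaly_sd_precip,
    anomaly_cor = anomaly_cor, corr_length = corr_length,
    noise_sd_tmax = noise_sd_tmax, noise_sd_tmean = noise_sd_tmean,
    noise_sd_precip = noise_sd_precip,
    lat0 = lat0, lon0 = lon0, seed = as.integer(seed)
  ), class = "csi_config")
}

cell_coords <- function(config) {
  lat <- config$lat0 + seq_len(config$n_lat) - 1
  lon <- config$lon0 + seq_len(config$n_lon) - 1
  expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
}

# Lower Cholesky factor of the exponential spatial correlation matrix.
spatial_chol <- function(coords, corr_length) {
  d <- as.matrix(stats::dist(coords[, c("lat", "lon")]))
  s <- exp(-d / corr_length)
  t(chol(s + diag(1e-9, nrow(s))))
}

# Deterministic seasonal cycles on each cell (mild north-south gradient).
seasonal_fields <- function(config) {
  coords <- cell_coords(config)
  lat_eff <- -0.4 * (coords$lat - config$lat0 - (config$n_lat - 1) / 2)
  doy <- seq_len(365)
  m <- 1:12
  list(
    tmax = outer(14.5 + 13 * cos(2 * pi * (doy - 201) / 365), lat_eff, "+"),
    tmean = outer(9 + 10.5 * cos(2 * pi * (m - 7.2) / 12), lat_eff, "+"),
    precip = matrix(70 - 18 * cos(2 * pi * (m - 7) / 12), 12, nrow(coords))
  )
}

# Stochastic anomaly fields: a spatially correlated draw per year x month
# shared by temperature variables (and coupled to precipitation), plus
# variable-specific white noise.  Consumes RNG state; caller seeds.
gen_anomaly_fields <- function(config, n_years) {
  nc <- config$n_lat * config$n_lon
  L <- spatial_chol(cell_coords(config), config$corr_length)
  nym <- n_years * 12L
  zT <- L %*% matrix(stats::rnorm(nc * nym), nc, nym)
  zP <- config$anomaly_cor * zT +
    sqrt(1 - config$anomaly_cor^2) * (L %*% matrix(stats::rnorm(nc * nym), nc, nym))
  # [year, month, cell]
  aT <- aperm(array(config$anomaly_sd_temp * zT, c(nc, 12, n_years)), c(3, 2, 1))
  aP <- aperm(array(config$anomaly_sd_precip * zP, c(nc, 12, n_years)), c(3, 2, 1))
  tmean_anom <- 0.8 * aT +
    array(stats::rnorm(n_years * 12 * nc, 0, config$noise_sd_tmean), dim(aT))
  precip_anom <- aP +
    array(stats::rnorm(n_years * 12 * nc, 0, config$noise_sd_precip), dim(aP))
  tmax_anom <- aT[, MONTH_OF_DOY, , drop = FALSE] +
    array(stats::rnorm(n_years * 365 * nc, 0, config$noise_sd_tmax),
          c(n_years, 365, nc))
  list(tmax = tmax_anom, tmean = tmean_anom, precip = precip_anom)
}

#' Generate a synthetic observed climate grid
#'
#' Daily maximum temperature, monthly mean temperature and monthly
#' precipitation on a regular lat/lon grid: a harmonic seasonal cycle plus
#' spatially correlated monthly anomaly fields plus cell-level noise.  The
#' summer daily-maximum distribution straddles the 30 degree heat threshold,
#' so heat degree days are large in hot years and can vanish in cool ones.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `csi_climate` with fields `tmax`
#'   (`[year, day-of-year, cell]`), `tmean` and `precip`
#'   (`[year, month, cell]`), coordinates, years, the seasonal cycles and the
#'   raw (pre-flooring) anomaly fields used for forecast generation.
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "csi_config"))
  if (config$n_years < 2) stop("configuration error: n_years < 2")
  set.seed(config$seed)
  seas <- seasonal_fields(config)
  an <- gen_anomaly_fields(config, config$n_years)
  ny <- config$n_years
  nc <- config$n_lat * config$n_lon
  expand_seas <- function(s, nt) aperm(array(s, c(nt, nc, ny)), c(3, 1, 2))
  tmax <- expand_seas(seas$tmax, 365) + an$tmax
  tmean <- expand_seas(seas$tmean, 12) + an$tmean
  precip <- pmax(expand_seas(seas$precip, 12) + an$precip, 0)
  structure(list(
    config = config, coords = cell_coords(config),
    years = 1980L + seq_len(ny),
    tmax = tmax, tmean = tmean, precip = precip,
    seasonal = seas, anom = an
  ), class = "csi_climate")
}

#' Generate a synthetic harvested-area crop mask
#'
#' Partitions the grid into contiguous country blocks (strips of longitude
#' columns) and assigns each cell a nonnegative harvested-area weight, drawn
#' once per configuration and normalised to sum to one within each country.
#' The unnormalised per-country totals act as the countries' maize cropland
#' areas in pooled verification.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `csi_cropmask`: a data frame `cells`
#'   (cell, country, weight) plus `country_area`, the per-country total area.
#' @export
generate_crop_mask <- function(config) {
  stopifnot(inherits(config, "csi_config"))
  nc <- config$n_lat * config$n_lon
  if (config$n_countries > nc) {
    stop("configuration error: more countries than grid cells")
  }
  set.seed(config$seed + 1L)
  col_grp <- ceiling(seq_len(config$n_lon) * config$n_countries / config$n_lon)
  coords <- cell_coords(config)
  cell_col <- rep(seq_len(config$n_lon), each = config$n_lat)
  country <- paste0("C", col_grp[cell_col])
  raw <- stats::rgamma(nc, shape = 2, rate = 1)
  weight <- stats::ave(raw, country, FUN = function(w) w / sum(w))
  cells <- data.frame(cell = seq_len(nc), lat = coords$lat, lon = coords$lon,
                      country = country, weight = weight, raw_area = raw,
                      stringsAsFactors = FALSE)
  area <- tapply(raw, country, sum)
  structure(list(cells = cells,
                 country_area = area[order(names(area))],
                 countries = sort(unique(country))),
            class = "csi_cropmask")
}

#' Generate synthetic national yield series with known climate sensitivity
#'
#' For each country the true standardised predictors are computed with the
#' production index code (cell-level HDD and SPEI at the configured window,
#' crop-weighted, de-trended/standardised), and log-yield is built as a
#' quadratic trend plus a linear climate signal plus Gaussian noise:
#' `log(yield_t) = log(y0) + c1 t + c2 t^2 + s (g_spei SPEI*_t + g_hdd HDD*_t + e_t)`
#' with `e_t ~ Normal(0, noise_sd)` and `s` the signal scale.
#'
#' @param climate a `csi_climate` object.
#' @param mask a `csi_cropmask` on the same grid.
#' @param config the [synth_config()] used to generate both.
#' @return list with `yields` (data frame: country, year, yield) and `truth`
#'   (per-country predictor series, coefficients, window, noise draws).
#' @export
generate_yields <- function(climate, mask, config) {
  stopifnot(inherits(climate, "csi_climate"), inherits(mask, "csi_cropmask"))
  if (nrow(mask$cells) != dim(climate$tmax)[3]) {
    stop("dimension error: crop mask and climate grids differ")
  }
  set.seed(config$seed + 2L)
  years <- climate$years
  tt <- years - mean(years)
  hdd_cells <- climate_hdd(climate, config$t_thr)
  sp <- climate_spei(climate, k = config$spei_k,
                     ending_month = config$spei_month)
  g <- config$yield_coeffs
  tr <- config$trend_coeffs
  out <- vector("list", length(mask$countries))
  truth <- list(coeffs = g, trend = tr, k = config$spei_k,
                ending_month = config$spei_month, noise_sd = config$noise_sd,
                countries = list())
  for (i in seq_along(mask$countries)) {
    cty <- mask$countries[i]
    hdd_c <- aggregate_to_country(hdd_cells, mask, cty)
    spei_c <- aggregate_to_country(sp$values, mask, cty)
    hdd_star <- detrend_standardise(hdd_c, years, standardise = TRUE)$values
    spei_star <- detrend_standardise(spei_c, years, standardise = FALSE)$values
    e <- stats::rnorm(length(years), 0, config$noise_sd)
    signal <- g[["spei"]] * spei_star + g[["hdd"]] * hdd_star
    logy <- log(6) + tr[["linear"]] * tt + tr[["quadratic"]] * tt^2 +
      config$signal_scale * (signal + e)
    out[[i]] <- data.frame(country = cty, year = years, yield = exp(logy),
                           stringsAsFactors = FALSE)
    truth$countries[[cty]] <- list(spei_star = spei_star,
                                   hdd_star = hdd_star,
                                   signal = signal, noise = e)
  }
  list(yields = do.call(rbind, out), truth = truth)
}

#' Generate a synthetic ensemble re-forecast experiment
#'
#' Each member's anomaly field is a mixture
#' `rho * observed anomaly + sqrt(1 - rho^2) * member noise`, where the member
#' noise is drawn from the same generative weather model as the observations,
#' then distorted by an additive bias and a multiplicative dispersion factor
#' so that quantile mapping has work to do.  A 4-month lead window starting
#' 1 May or 1 June covers the June-August target season.
#'
#' @param climate the observed `csi_climate` truth.
#' @param config the shared [synth_config()].
#' @param start_month forecast initialisation month, 5 (May) or 6 (June).
#' @param skill_rho member-truth anomaly correlation; defaults to the config
#'   value.  Use ~0 for a CLIM-like and ~0.8 for an INIT-like experiment.
#' @param bias_temp,bias_precip,dispersion distortion knobs; default to the
#'   config values.
#' @param seed RNG seed for the member noise; defaults to a start-month
#'   specific offset of the config seed so experiments sharing a start month
#'   share member noise (common random numbers across skill levels).
#' @return an object of class `csi_forecast`: arrays `tmax`
#'   (`[member, year, window-day, cell]`), `tmean`, `precip`
#'   (`[member, year, window-month, cell]`), the window months/doys and the
#'   generation settings.
#' @export
generate_forecasts <- function(climate, config, start_month = 5,
                               skill_rho = config$skill_rho,
                               bias_temp = config$bias_temp,
                               bias_precip = config$bias_precip,
                               dispersion = config$dispersion,
                               seed = config$seed + 17L * start_month) {
  stopifnot(inherits(climate, "csi_climate"))
  if (!start_month %in% c(5, 6)) stop("configuration error: start_month must be 5 or 6")
  if (!is.finite(skill_rho) || skill_rho < 0 || skill_rho > 1) {
    stop("configuration error: skill_rho must lie in [0, 1]")
  }
  months <- start_month:(start_month + 3)
  wdoys <- which(MONTH_OF_DOY %in% months)
  ny <- config$n_years
  nc <- config$n_lat * config$n_lon
  nm <- config$n_members
  seas <- climate$seasonal
  rho <- skill_rho
  mix <- sqrt(1 - rho^2)
  tmax <- array(NA_real_, c(nm, ny, length(wdoys), nc))
  tmean <- array(NA_real_, c(nm, ny, length(months), nc))
  precip <- array(NA_real_, c(nm, ny, length(months), nc))
  seas_tmax <- aperm(array(seas$tmax[wdoys, ], c(length(wdoys), nc, ny)), c(3, 1, 2))
  seas_tmean <- aperm(array(seas$tmean[months, ], c(length(months), nc, ny)), c(3, 1, 2))
  seas_precip <- aperm(array(seas$precip[months, ], c(length(months), nc, ny)), c(3, 1, 2))
  set.seed(seed)
  for (mem in seq_len(nm)) {
    man <- gen_anomaly_fields(config, ny)
    tmax[mem, , , ] <- seas_tmax + bias_temp + dispersion *
      (rho * climate$anom$tmax[, wdoys, , drop = FALSE] +
         mix * man$tmax[, wdoys, , drop = FALSE])
    tmean[mem, , , ] <- seas_tmean + bias_temp + dispersion *
      (rho * climate$anom$tmean[, months, , drop = FALSE] +
         mix * man$tmean[, months, , drop = FALSE])
    precip[mem, , , ] <- pmax(seas_precip + bias_precip + dispersion *
      (rho * climate$anom$precip[, months, , drop = FALSE] +
         mix * man$precip[, months, , drop = FALSE]), 0)
  }
  structure(list(
    start_month = as.integer(start_month), months = months, wdoys = wdoys,
    years = climate$years, tmax = tmax, tmean = tmean, precip = precip,
    skill_rho = skill_rho, bias_temp = bias_temp, bias_precip = bias_precip,
    dispersion = dispersion, corrected = FALSE
  ), class = "csi_forecast")
}
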