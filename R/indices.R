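# Agro-climatic predictors: heat degree days (HDD) and the standardised
# precipitation-evapotranspiration index (SPEI), computed per grid cell and
# aggregated to country level with crop-area weights.

#' Heat degree days for one summer at one cell
#'
#' Sum of daily maximum-temperature exceedances over a threshold across the
#' June-August days: `sum_i max(tmax_i - t_thr, 0)`, in degree-days.  The
#' threshold defaults to 30 degrees C, just above the optimum temperature
#' range for maize growth processes.
#'
#' @param tmax numeric vector of daily maximum temperatures for the summer
#'   days of one year at one cell.
#' @param t_thr threshold temperature, degrees C (default 30).
#' @param max_missing maximum tolerated fraction of missing days.
#' @param on_missing `"error"` (default) to fail on excess missingness,
#'   `"na"` to return `NA` so that the cell-year can be dropped and weights
#'   renormalised during aggregation.
#' @return heat degree days (degree C * day), >= 0.
#' @export
compute_hdd_cell <- function(tmax, t_thr = 30, max_missing = 0.05,
                             on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  if (!is.finite(t_thr)) stop("t_thr must be finite")
  bad <- !is.finite(tmax)
  if (mean(bad) > max_missing) {
    if (on_missing == "error") {
      stop("data-completeness error: more than ", 100 * max_missing,
           "% of summer days missing")
    }
    return(NA_real_)
  }
  sum(pmax(tmax[!bad] - t_thr, 0))
}

# HDD for every cell-year of a climate grid: matrix [year, cell].
climate_hdd <- function(climate, t_thr = 30) {
  x <- pmax(climate$tmax[, JJA_DOYS, , drop = FALSE] - t_thr, 0)
  apply(x, c(1, 3), sum)
}

#' Thornthwaite potential evapotranspiration
#'
#' Temperature-only monthly PET: `16 * (N/12) * (days/30) * (10 T / I)^a` with
#' the annual heat index `I = sum (T_m/5)^1.514` over months with `T_m > 0`
#' and the cubic exponent `a(I)`; PET is zero for months at or below 0
#' degrees C.  Daylength `N` uses the standard mid-month solar declination.
#'
#' @param tmean monthly mean temperatures (degrees C): a vector whose length
#'   is a multiple of 12 (January-first), or a `[year, 12]` matrix.
#' @param lat latitude in degrees, in [-90, 90].
#' @return PET in mm/month, same shape as the input.
#' @export
compute_pet <- function(tmean, lat) {
  if (!is.finite(lat) || abs(lat) > 90) stop("domain error: latitude outside [-90, 90]")
  vec_in <- is.null(dim(tmean))
  tm <- if (vec_in) {
    if (length(tmean) %% 12 != 0) stop("tmean length must be a multiple of 12")
    matrix(tmean, ncol = 12, byrow = TRUE)
  } else {
    if (ncol(tmean) != 12) stop("tmean matrix must have 12 columns")
    tmean
  }
  I <- rowSums((pmax(tm, 0) / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  mid <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2
  delta <- 0.409 * sin(2 * pi * mid / 365 - 1.39)
  omega <- acos(pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(delta))))
  K <- (24 * omega / pi / 12) * (DAYS_IN_MONTH / 30)   # length 12
  pet <- matrix(0, nrow(tm), 12)
  ok <- tm > 0 & I > 0
  if (any(ok)) {
    base <- 16 * (10 * tm / I)^a          # recycles I, a by row
    pet[ok] <- (base * rep(K, each = nrow(tm)))[ok]
  }
  if (vec_in) as.vector(t(pet)) else pet
}

# Probability-weighted-moment fit of the three-parameter log-logistic
# distribution, the standard SPEI formulation.  Falls back to an empirical
# plotting-position transform when the fit is invalid (needs beta > 1 for
# finite moments).
spei_fit <- function(d_ref) {
  x <- sort(d_ref)
  n <- length(x)
  i <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum(x * (n - i) / (n * (n - 1)))
  w2 <- sum(x * (n - i) * (n - i - 1) / (n * (n - 1) * (n - 2)))
  beta <- (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
  fit <- NULL
  if (is.finite(beta) && beta > 1) {
    gg <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
    alpha <- (w0 - 2 * w1) * beta / gg
    gamma_loc <- w0 - alpha * gg
    if (is.finite(alpha) && alpha > 0 && is.finite(gamma_loc)) {
      fit <- list(type = "loglogistic", alpha = alpha, beta = beta,
                  gamma = gamma_loc)
    }
  }
  if (is.null(fit)) {
    fit <- list(type = "empirical", ref = x)
  }
  fit
}

# Map water-balance values through a fitted distribution to standard-normal
# deviates.  Probabilities are clamped away from 0/1 so extremes stay finite.
spei_transform <- function(d, fit, p_clamp = 5e-4) {
  if (fit$type == "loglogistic") {
    p <- ifelse(d > fit$gamma,
                1 / (1 + (fit$alpha / (d - fit$gamma))^fit$beta),
                0)
  } else {
    n <- length(fit$ref)
    pp <- (seq_len(n) - 0.44) / (n + 0.12)  # Gringorten plotting positions
    p <- stats::approx(fit$ref, pp, xout = d, rule = 2, ties = "ordered")$y
  }
  stats::qnorm(pmin(pmax(p, p_clamp), 1 - p_clamp))
}

#' Standardised precipitation-evapotranspiration index at one cell
#'
#' Aggregates the monthly climatic water balance `D = P - PET` over the `k`
#' months ending at `ending_month` of each year, fits a three-parameter
#' log-logistic distribution to the reference-period values by unbiased
#' probability-weighted moments, and transforms each year's balance to a
#' standard-normal deviate.  If the parametric fit is invalid an empirical
#' plotting-position standardisation is used instead.
#'
#' @param precip,pet `[year, 12]` matrices of monthly precipitation and PET
#'   (mm/month).
#' @param k aggregation timescale in months (1, 2 or 3).
#' @param ending_month last month of the window (6, 7 or 8).
#' @param ref_years indices of the reference years for the fit (default all);
#'   at least 20 required.
#' @return list with `spei` (one value per year), the aggregated balance `d`,
#'   the fitted distribution `fit`, and the window.
#' @export
compute_spei <- function(precip, pet, k, ending_month, ref_years = NULL) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  if (!ending_month %in% 6:8) stop("ending_month must be June (6), July (7) or August (8)")
  if (!all(dim(precip) == dim(pet))) stop("precip and pet dimensions differ")
  months <- (ending_month - k + 1):ending_month
  d <- rowSums(precip[, months, drop = FALSE] - pet[, months, drop = FALSE])
  if (any(!is.finite(d))) stop("data error: non-finite water balance")
  if (is.null(ref_years)) ref_years <- seq_along(d)
  if (length(ref_years) < 20) stop("insufficient-data error: fewer than 20 reference years")
  fit <- spei_fit(d[ref_years])
  list(spei = spei_transform(d, fit), d = d, fit = fit, k = k,
       ending_month = ending_month)
}

# SPEI for every cell of a climate grid at one (k, ending month) candidate.
# Returns the [year, cell] value matrix plus the per-cell fits (reused to
# transform bias-corrected forecast members onto the observed climatology).
climate_spei <- function(climate, k, ending_month, ref_years = NULL) {
  nc <- dim(climate$tmean)[3]
  ny <- dim(climate$tmean)[1]
  values <- matrix(NA_real_, ny, nc)
  fits <- vector("list", nc)
  pet_all <- vector("list", nc)
  for (cc in seq_len(nc)) {
    pet <- compute_pet(climate$tmean[, , cc], climate$coords$lat[cc])
    s <- compute_spei(climate$precip[, , cc], pet, k, ending_month, ref_years)
    values[, cc] <- s$spei
    fits[[cc]] <- s$fit
    pet_all[[cc]] <- pet
  }
  list(values = values, fits = fits, pet = pet_all, k = k,
       ending_month = ending_month)
}

#' Crop-area-weighted aggregation of cell values to country level
#'
#' Weighted mean of a per-cell field using the country's normalised
#' harvested-area weights.  Cell-years flagged `NA` are dropped and the
#' remaining weights renormalised.
#'
#' @param values a `[year, cell]` matrix (or a single-cell-dimension vector).
#' @param mask a `csi_cropmask`.
#' @param country country identifier present in the mask.
#' @return numeric vector, one value per year.
#' @export
aggregate_to_country <- function(values, mask, country) {
  stopifnot(inherits(mask, "csi_cropmask"))
  if (!country %in% mask$countries) stop("unknown country: ", country)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  w <- numeric(ncol(values))
  sel <- mask$cells$country == country
  w[mask$cells$cell[sel]] <- mask$cells$weight[sel]
  if (sum(w) <= 0) stop("configuration error: zero total weight for ", country)
  ok <- is.finite(values)
  wm <- matrix(w, nrow(values), ncol(values), byrow = TRUE)
  wm[!ok] <- 0
  tot <- rowSums(wm)
  if (any(tot <= 0)) stop("configuration error: no valid cells for ", country)
  vals <- values
  vals[!ok] <- 0
  drop(rowSums(vals * wm) / tot)
}
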