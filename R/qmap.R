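# Non-parametric quantile mapping: empirical-quantile transfer functions that
# map forecast variables onto the observed climatology before the indices are
# computed.  Monthly precipitation, monthly mean temperature and daily
# maximum temperature are corrected, stratified per start month, calendar
# month and grid cell, with ensemble members pooled.

#' Fit a non-parametric quantile-mapping transfer function
#'
#' Empirical quantiles at evenly spaced probabilities are computed for the
#' pooled model sample and the observed sample; the correction is the
#' piecewise-linear map between the paired quantiles.
#'
#' @param model_values pooled (all members, all years) forecast sample.
#' @param obs_values observed sample for the same stratum.
#' @param n_quantiles number of quantile knots (default 21); reduced with a
#'   warning when a sample is smaller than the knot count.
#' @param floor_zero floor corrected values at zero (for precipitation).
#' @return object of class `csi_qmap` with the paired knots.
#' @export
fit_qmap <- function(model_values, obs_values, n_quantiles = 21,
                     floor_zero = FALSE) {
  model_values <- model_values[is.finite(model_values)]
  obs_values <- obs_values[is.finite(obs_values)]
  n_min <- min(length(model_values), length(obs_values))
  if (n_min < 5) stop("insufficient-data error: need at least 5 values per side")
  if (n_min < n_quantiles) {
    warning("fewer samples than quantiles; reducing knot count to ", n_min)
    n_quantiles <- n_min
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  # inverse-ECDF quantiles with an explicit index rule: invariant under
  # member pooling of identical samples, so an unbiased ensemble maps onto
  # the identity
  q1 <- function(x, p) {
    xs <- sort(x)
    n <- length(xs)
    xs[pmin(n, pmax(1, ceiling(n * p - 1e-9)))]
  }
  src <- q1(model_values, probs)
  tgt <- q1(obs_values, probs)
  # collapse duplicated source knots (ties, e.g. dry months) keeping the map
  # monotone non-decreasing
  keep <- !duplicated(src)
  if (sum(keep) < 2) {
    src <- src[c(1, length(src))] + c(0, 1e-9)
    tgt <- tgt[c(1, length(tgt))]
  } else {
    tgt <- unname(vapply(split(tgt, match(src, src[keep])), mean, numeric(1)))
    src <- src[keep]
  }
  structure(list(source = src, target = tgt, floor_zero = floor_zero),
            class = "csi_qmap")
}

#' Apply a quantile-mapping correction
#'
#' Piecewise-linear interpolation between the fitted quantile knots; values
#' beyond the training range are shifted by the constant offset of the
#' terminal knot pair.  Precipitation maps floor the corrected values at 0.
#'
#' @param map a `csi_qmap`.
#' @param values values to correct (any shape).
#' @return corrected values, same shape.
#' @export
apply_qmap <- function(map, values) {
  stopifnot(inherits(map, "csi_qmap"))
  if (any(!is.finite(values))) stop("data error: non-finite input values")
  src <- map$source
  tgt <- map$target
  out <- stats::approx(src, tgt, xout = pmin(pmax(values, src[1]), src[length(src)]),
                       ties = "ordered")$y
  lo <- values < src[1]
  hi <- values > src[length(src)]
  out[lo] <- values[lo] + (tgt[1] - src[1])
  out[hi] <- values[hi] + (tgt[length(tgt)] - src[length(src)])
  if (map$floor_zero) out <- pmax(out, 0)
  dim(out) <- dim(values)
  out
}

#' Bias-correct a synthetic ensemble re-forecast
#'
#' Fits and applies quantile maps per variable, calendar month and grid cell,
#' pooling ensemble members on the forecast side, against the observed
#' climatology of the same months.  Daily maximum temperature pools the days
#' of each June-August month.
#'
#' @param forecast a `csi_forecast`.
#' @param climate the observed `csi_climate`.
#' @param n_quantiles quantile knots per map (default 21).
#' @return the corrected `csi_forecast` (`corrected = TRUE`).
#' @export
bias_correct_forecast <- function(forecast, climate, n_quantiles = 21) {
  stopifnot(inherits(forecast, "csi_forecast"), inherits(climate, "csi_climate"))
  nm <- dim(forecast$tmean)[1]
  nc <- dim(forecast$tmean)[4]
  out <- forecast
  for (cc in seq_len(nc)) {
    for (wi in seq_along(forecast$months)) {
      m <- forecast$months[wi]
      qm_t <- fit_qmap(as.vector(forecast$tmean[, , wi, cc]),
                       climate$tmean[, m, cc], n_quantiles)
      out$tmean[, , wi, cc] <- apply_qmap(qm_t, forecast$tmean[, , wi, cc])
      qm_p <- fit_qmap(as.vector(forecast$precip[, , wi, cc]),
                       climate$precip[, m, cc], n_quantiles, floor_zero = TRUE)
      out$precip[, , wi, cc] <- apply_qmap(qm_p, forecast$precip[, , wi, cc])
    }
    for (m in intersect(forecast$months, 6:8)) {
      wd <- which(MONTH_OF_DOY[forecast$wdoys] == m)
      od <- which(MONTH_OF_DOY %in% m)
      qm_x <- fit_qmap(as.vector(forecast$tmax[, , wd, cc]),
                       as.vector(climate$tmax[, od, cc]), n_quantiles)
      out$tmax[, , wd, cc] <- apply_qmap(qm_x, forecast$tmax[, , wd, cc])
    }
  }
  out$corrected <- TRUE
  out
}
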