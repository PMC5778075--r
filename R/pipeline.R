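# End-to-end orchestration: observed calibration (climate indices ->
# detrending -> CSI model with window optimisation and significance) and
# forecast verification (bias correction -> member indices -> ensemble CSI ->
# reliability / ROC / ETS).

candidate_windows <- function(k_set = 1:3, ending_months = 6:8) {
  # (k, month)-lexicographic order: the tie-break order of the optimiser
  out <- expand.grid(ending_month = ending_months, k = k_set)[, c("k", "ending_month")]
  out[order(out$k, out$ending_month), ]
}

#' Calibrate country-level CSI models from observed climate and yields
#'
#' Chains the full observed-climate analysis: cell-level HDD and SPEI (all
#' timescale x ending-month candidates), crop-weighted country aggregation,
#' de-trending/standardisation, leave-one-out ridge calibration with SPEI
#' window optimisation, and a permutation significance test.  Countries with
#' fewer than `min_years` yield years, degenerate series, or non-significant
#' models are excluded (with recorded reasons) from downstream forecast
#' verification.
#'
#' @param climate a `csi_climate`.
#' @param mask a `csi_cropmask` on the same grid.
#' @param yields data frame with columns country, year, yield.
#' @param t_thr HDD temperature threshold (degrees C, default 30).
#' @param k_set,ending_months SPEI window candidate set (default 1-3 months
#'   ending June-August).
#' @param lambda_grid ridge penalty grid.
#' @param min_years minimum yield-series length for inclusion (default 20).
#' @param significance run the permutation test and gate countries on it
#'   (default TRUE).
#' @param B,alpha permutation count and level for the significance test.
#' @param gate_on_mk only remove trends significant under Mann-Kendall.
#' @param seed RNG seed (permutation tests).
#' @return object of class `csi_calibration`: per-country records (model,
#'   trend fits and scales, observed CSI series, event threshold,
#'   significance), the Q^2 table, stress-area fractions over significant
#'   countries, and the per-candidate cell-level SPEI fits needed to
#'   transform forecasts.
#' @export
calibrate_csi <- function(climate, mask, yields, t_thr = 30,
                          k_set = 1:3, ending_months = 6:8,
                          lambda_grid = default_lambda_grid(),
                          min_years = 20, significance = TRUE,
                          B = 500, alpha = 0.05, gate_on_mk = FALSE,
                          seed = 1L) {
  stopifnot(inherits(climate, "csi_climate"), inherits(mask, "csi_cropmask"))
  years <- climate$years
  hdd_cells <- climate_hdd(climate, t_thr)
  cand <- candidate_windows(k_set, ending_months)
  spei_grids <- lapply(seq_len(nrow(cand)), function(i) {
    climate_spei(climate, cand$k[i], cand$ending_month[i])
  })
  names(spei_grids) <- sprintf("k%d_m%d", cand$k, cand$ending_month)
  records <- list()
  for (ci in seq_along(mask$countries)) {
    cty <- mask$countries[ci]
    ydf <- yields[yields$country == cty, , drop = FALSE]
    rec <- list(country = cty, included = FALSE, reason = NA_character_)
    if (nrow(ydf) < min_years) {
      rec$reason <- sprintf("only %d yield years (< %d)", nrow(ydf), min_years)
      records[[cty]] <- rec
      next
    }
    iy <- match(ydf$year, years)
    if (any(is.na(iy))) stop("yield years outside the climate period for ", cty)
    hdd_c <- aggregate_to_country(hdd_cells, mask, cty)
    hd <- detrend_standardise(hdd_c, years, standardise = TRUE,
                              gate_on_mk = gate_on_mk)
    spei_stars <- lapply(spei_grids, function(sg) {
      s <- aggregate_to_country(sg$values, mask, cty)
      detrend_standardise(s, years, standardise = FALSE,
                          gate_on_mk = gate_on_mk)
    })
    yfit <- detrend_standardise(ydf$yield, ydf$year, transform = "log",
                                standardise = TRUE, gate_on_mk = gate_on_mk)
    cands <- lapply(seq_len(nrow(cand)), function(i) {
      list(values = spei_stars[[i]]$values[iy], k = cand$k[i],
           ending_month = cand$ending_month[i])
    })
    model <- optimise_spei_choice(yfit$values, cands, hd$values[iy],
                                  lambda_grid, country = cty)
    key <- sprintf("k%d_m%d", model$k, model$ending_month)
    sig <- if (significance) {
      significance_test(model, B = B, alpha = alpha, seed = seed + ci)
    } else {
      list(significant = TRUE, p = NA_real_)
    }
    csi_obs <- predict_csi(model, spei_stars[[key]]$values, hd$values)
    rec <- c(rec, list(
      model = model, significant = sig$significant, p_value = sig$p,
      hdd_series = hd$values, hdd_fit = hd$fit, hdd_sd = hd$sd,
      spei_series = spei_stars[[key]]$values,
      spei_trend_fit = spei_stars[[key]]$fit,
      yield_fit = yfit$fit, yield_sd = yfit$sd,
      y_std = yfit$values, yield_years = ydf$year,
      csi_obs = csi_obs, threshold = event_threshold(csi_obs)
    ))
    rec$included <- sig$significant
    if (!sig$significant) rec$reason <- "CSI model not significant"
    records[[cty]] <- rec
  }
  inc <- names(records)[vapply(records, `[[`, logical(1), "included")]
  q2_table <- do.call(rbind, lapply(records, function(r) {
    data.frame(country = r$country,
               q2 = if (is.null(r$model)) NA_real_ else r$model$q2,
               significant = isTRUE(r$significant),
               reason = r$reason, stringsAsFactors = FALSE)
  }))
  rownames(q2_table) <- NULL
  stress <- if (length(inc) > 0) {
    classify_stress_area(
      sapply(inc, function(c) records[[c]]$spei_series),
      sapply(inc, function(c) records[[c]]$hdd_series),
      mask$country_area[inc]
    )
  } else {
    NULL
  }
  structure(list(
    records = records, included = inc, q2_table = q2_table, stress = stress,
    years = years, spei_grids = spei_grids, candidates = cand,
    t_thr = t_thr, seed = seed
  ), class = "csi_calibration")
}

# Member HDD per cell from a (corrected) forecast: [member, year, cell].
forecast_member_hdd <- function(forecast, t_thr = 30) {
  jd <- which(MONTH_OF_DOY[forecast$wdoys] %in% 6:8)
  x <- pmax(forecast$tmax[, , jd, , drop = FALSE] - t_thr, 0)
  apply(x, c(1, 2, 4), sum)
}

# Member SPEI per cell for one window candidate, using the observation-fitted
# cell distributions.  Months of the window that precede the forecast start
# are spliced from the observations (monitoring data available at
# initialisation); the Thornthwaite heat index likewise uses the member
# months spliced into the observed year.
forecast_member_spei <- function(forecast, climate, spei_grid) {
  k <- spei_grid$k
  m <- spei_grid$ending_month
  need <- (m - k + 1):m
  wm <- intersect(need, forecast$months)
  wi <- match(wm, forecast$months)
  nm <- dim(forecast$tmean)[1]
  ny <- dim(forecast$tmean)[2]
  nc <- dim(forecast$tmean)[4]
  out <- array(NA_real_, c(nm, ny, nc))
  for (mem in seq_len(nm)) {
    for (cc in seq_len(nc)) {
      tm <- climate$tmean[, , cc]
      pr <- climate$precip[, , cc]
      tm[, wm] <- forecast$tmean[mem, , wi, cc]
      pr[, wm] <- forecast$precip[mem, , wi, cc]
      pet <- compute_pet(tm, climate$coords$lat[cc])
      d <- rowSums(pr[, need, drop = FALSE] - pet[, need, drop = FALSE])
      out[mem, , cc] <- spei_transform(d, spei_grid$fits[[cc]])
    }
  }
  out
}

#' Verify CSI re-forecasts against the observed calibration
#'
#' For each re-forecast experiment: quantile-map the forecast variables onto
#' the observed climatology, compute member-wise HDD and SPEI (at each
#' country's optimised window, transformed with the observation-fitted
#' distributions), convert them to anomalies with the observation-derived
#' trend fits and scales, push them through the calibrated CSI models, and
#' score the resulting probabilistic low-yield forecasts: ensemble-mean
#' correlations, pooled area-weighted reliability and ROC/ROCSS with
#' bootstrap intervals, and per-country ETS at member-fraction thresholds.
#'
#' @param calibration a `csi_calibration`; only its significant countries are
#'   scored.
#' @param climate the observed `csi_climate`.
#' @param mask the `csi_cropmask`.
#' @param forecasts named list of `csi_forecast` experiments
#'   (e.g. INIT05, CLIM05, ...).
#' @param member_fractions decision thresholds for the ETS contingency
#'   (default 0.5-0.8).
#' @param bias_correct apply quantile mapping first (default TRUE).
#' @param n_quantiles quantile-map knots.
#' @param R,level bootstrap replicates and interval coverage.
#' @param seed RNG seed for the bootstrap resampling.
#' @return object of class `csi_verification`: per experiment, correlation
#'   table, pooled probability forecasts, reliability, ROC and ETS tables.
#' @export
verify_forecasts <- function(calibration, climate, mask, forecasts,
                             member_fractions = c(0.5, 0.6, 0.7, 0.8),
                             bias_correct = TRUE, n_quantiles = 21,
                             R = 1000, level = 0.75, seed = 1L) {
  stopifnot(inherits(calibration, "csi_calibration"))
  inc <- calibration$included
  if (length(inc) == 0) stop("no significant CSI models to verify")
  years <- calibration$years
  reports <- list()
  for (ei in seq_along(forecasts)) {
    ename <- names(forecasts)[ei]
    fc <- forecasts[[ei]]
    if (bias_correct) fc <- bias_correct_forecast(fc, climate, n_quantiles)
    hdd_m <- forecast_member_hdd(fc, calibration$t_thr)
    keys <- unique(vapply(inc, function(c) {
      md <- calibration$records[[c]]$model
      sprintf("k%d_m%d", md$k, md$ending_month)
    }, character(1)))
    spei_m <- lapply(keys, function(k) {
      forecast_member_spei(fc, climate, calibration$spei_grids[[k]])
    })
    names(spei_m) <- keys
    nm <- dim(hdd_m)[1]
    pooled <- list()
    cors <- list()
    ets_rows <- list()
    csi_fc <- list()
    for (cty in inc) {
      rec <- calibration$records[[cty]]
      key <- sprintf("k%d_m%d", rec$model$k, rec$model$ending_month)
      hdd_cty <- t(vapply(seq_len(nm), function(mm) {
        aggregate_to_country(hdd_m[mm, , ], mask, cty)
      }, numeric(length(years))))
      spei_cty <- t(vapply(seq_len(nm), function(mm) {
        aggregate_to_country(spei_m[[key]][mm, , ], mask, cty)
      }, numeric(length(years))))
      hdd_anom <- (hdd_cty - matrix(predict(rec$hdd_fit, years), nm,
                                    length(years), byrow = TRUE)) / rec$hdd_sd
      spei_anom <- spei_cty - matrix(predict(rec$spei_trend_fit, years), nm,
                                     length(years), byrow = TRUE)
      ens <- ensemble_csi(spei_anom, hdd_anom, rec$model)
      iy <- match(rec$yield_years, years)
      cor_csi <- correlation_skill(ens$mean, rec$csi_obs)
      cor_y <- correlation_skill(ens$mean[iy], rec$y_std)
      cors[[cty]] <- data.frame(
        experiment = ename, country = cty,
        r_csi = cor_csi$r, p_csi = cor_csi$p, sig_csi = cor_csi$significant,
        r_yield = cor_y$r, p_yield = cor_y$p, sig_yield = cor_y$significant,
        stringsAsFactors = FALSE)
      probs <- event_probabilities(ens$member, rec$csi_obs, rec$threshold)
      probs$country <- cty
      probs$weight <- unname(mask$country_area[cty])
      pooled[[cty]] <- probs
      csi_fc[[cty]] <- ens$mean
      for (f in member_fractions) {
        ct <- contingency_from_probs(probs$prob, probs$outcome, f)
        ets_rows[[paste(cty, f)]] <- data.frame(
          experiment = ename, country = cty, member_fraction = f,
          j = ct[["j"]], k = ct[["k"]], l = ct[["l"]], m = ct[["m"]],
          ets = ets(ct[["j"]], ct[["k"]], ct[["l"]], ct[["m"]]),
          stringsAsFactors = FALSE)
      }
    }
    pool <- do.call(rbind, pooled)
    rel <- reliability_diagram(pool$prob, pool$outcome, pool$weight,
                               R = R, level = level, seed = seed + 101L * ei)
    roc <- roc_and_rocss(pool$prob, pool$outcome, pool$weight,
                         R = R, level = level, seed = seed + 101L * ei + 1L)
    reports[[ename]] <- list(
      experiment = ename,
      correlations = do.call(rbind, c(cors, list(make.row.names = FALSE))),
      forecasts = pool, csi_forecast = csi_fc,
      reliability = rel, roc = roc,
      ets = do.call(rbind, c(ets_rows, list(make.row.names = FALSE)))
    )
  }
  structure(list(reports = reports, countries = inc, seed = seed),
            class = "csi_verification")
}
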