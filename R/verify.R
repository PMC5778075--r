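# Probabilistic verification of low-yield (CSI_low) forecasts: ensemble CSI,
# correlation skill, reliability diagrams with count-weighted regression, ROC
# curves and the ROC skill score, the Equitable Threat Score, bootstrap
# confidence intervals, and the heat/drought stress-area classification.

#' Member-wise and ensemble-mean CSI
#'
#' Pushes bias-corrected, anomaly-converted member indices through a fitted
#' CSI model.  The model is linear, so the mean of the member CSIs equals the
#' CSI of the member-mean indices.
#'
#' @param member_spei,member_hdd `[member, year]` matrices of forecast
#'   predictor anomalies (on the observation-derived scale).
#' @param model a `csi_model`.
#' @return list with `member` (`[member, year]` CSI) and `mean` (per year).
#' @export
ensemble_csi <- function(member_spei, member_hdd, model) {
  if (!all(dim(member_spei) == dim(member_hdd))) {
    stop("completeness error: member index dimensions differ")
  }
  member <- predict_csi(model, member_spei, member_hdd)
  list(member = member, mean = colMeans(member))
}

#' Pearson correlation skill with significance
#'
#' @param forecast,reference paired annual series (>= 10 years).
#' @param alpha significance level (default 0.05).
#' @return list with `r`, `p` (two-sided t-test) and `significant`.
#' @export
correlation_skill <- function(forecast, reference, alpha = 0.05) {
  if (length(forecast) < 10) stop("insufficient-data error: need >= 10 paired years")
  if (stats::sd(forecast) < 1e-12 || stats::sd(reference) < 1e-12) {
    stop("undefined-correlation error: constant series")
  }
  ct <- stats::cor.test(forecast, reference, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < alpha)
}

#' Low-yield event threshold
#'
#' The 25th percentile (linear interpolation between order statistics) of the
#' observed CSI series, per country.
#'
#' @param csi_obs observed CSI series.
#' @param q quantile defining the event (default 0.25).
#' @return threshold value.
#' @export
event_threshold <- function(csi_obs, q = 0.25) {
  stats::quantile(csi_obs, q, names = FALSE, type = 7)
}

#' Probabilistic low-yield forecasts from a member CSI set
#'
#' Forecast probability = fraction of ensemble members with CSI below the
#' observed-climate threshold; outcome = 1 when the observed CSI fell below
#' it.
#'
#' @param member_csi `[member, year]` matrix of member CSI values.
#' @param csi_obs observed CSI series (length = years).
#' @param threshold event threshold from [event_threshold()].
#' @return data frame with `year` index, `prob` and binary `outcome`.
#' @export
event_probabilities <- function(member_csi, csi_obs, threshold) {
  if (ncol(member_csi) != length(csi_obs)) {
    stop("completeness error: member years do not match observations")
  }
  data.frame(year = seq_along(csi_obs),
             prob = colMeans(member_csi < threshold),
             outcome = as.integer(csi_obs < threshold))
}

weighted_contingency <- function(prob, outcome, threshold, weight) {
  f <- prob >= threshold
  o <- outcome > 0
  c(j = sum(weight[f & o]), k = sum(weight[f & !o]),
    l = sum(weight[!f & o]), m = sum(weight[!f & !o]))
}

#' Equitable Threat Score
#'
#' `ETS = (j - j_r) / (j + k + l - j_r)` with the random-hit correction
#' `j_r = (j + l)(j + k) / (j + k + l + m)`; 1 for a perfect forecast, about
#' 0 for random forecasts.  Undefined tables (zero denominator, e.g. all
#' correct negatives) return `NA`.
#'
#' @param j hits, `k` false alarms, `l` misses, `m` correct negatives.
#'   Vectorised.
#' @return the score (or `NA` where undefined).
#' @export
ets <- function(j, k, l, m) {
  if (any(c(j, k, l, m) < 0)) stop("contingency counts must be nonnegative")
  n <- j + k + l + m
  jr <- ifelse(n > 0, (j + l) * (j + k) / n, NA_real_)
  den <- j + k + l - jr
  ifelse(is.na(den) | abs(den) < 1e-12, NA_real_, (j - jr) / den)
}

#' Contingency table from probability forecasts
#'
#' A low-yield event is considered forecast when at least `member_fraction`
#' of the ensemble members predict it; forecasts are cross-tabulated against
#' the observed outcomes.
#'
#' @param prob forecast probabilities (member fractions).
#' @param outcome binary observed outcomes.
#' @param member_fraction decision threshold (0.5, 0.6, 0.7 or 0.8 in the
#'   standard sweep).
#' @param weight optional case weights (default 1).
#' @return named vector `c(j, k, l, m)`.
#' @export
contingency_from_probs <- function(prob, outcome, member_fraction,
                                   weight = rep(1, length(prob))) {
  weighted_contingency(prob, outcome, member_fraction, weight)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples case indices with replacement, recomputes the statistic, and
#' returns the percentile interval of the resampling distribution (default
#' the 75% interval from 1000 replicates).
#'
#' @param n number of cases to resample.
#' @param statistic function of an index vector returning a scalar (may
#'   return `NA` for degenerate resamples).
#' @param R replicates (default 1000).
#' @param level interval coverage (default 0.75).
#' @param seed optional RNG seed.
#' @return list with `lower`, `upper`, `level` and the resampled `values`.
#' @export
bootstrap_ci <- function(n, statistic, R = 1000, level = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(R), function(i) {
    statistic(sample.int(n, n, replace = TRUE))
  }, numeric(1))
  ok <- is.finite(vals)
  if (mean(ok) < 0.5) stop("bootstrap failure: statistic undefined on > 50% of resamples")
  qs <- stats::quantile(vals[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, values = vals)
}

reliability_bins <- function(prob, outcome, weight, n_bins) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(prob, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = breaks[-(n_bins + 1)], upper = breaks[-1],
                    forecast = NA_real_, observed = NA_real_, weight = 0)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    if (!any(sel)) next
    w <- weight[sel]
    out$weight[b] <- sum(w)
    out$forecast[b] <- sum(w * prob[sel]) / sum(w)
    out$observed[b] <- sum(w * outcome[sel]) / sum(w)
  }
  out
}

reliability_slope <- function(bins) {
  ok <- bins$weight > 0
  if (sum(ok) < 2) return(NA_real_)
  fit <- stats::lm(observed ~ forecast, data = bins[ok, ], weights = bins$weight[ok])
  unname(stats::coef(fit)[2])
}

#' Reliability diagram with count-weighted regression
#'
#' Pools probability forecasts (typically across countries, weighted by maize
#' cropland area), groups them into bins, and computes per-bin weighted mean
#' forecast probability and observed frequency.  A linear regression of
#' observed frequency on forecast probability, weighted by the pooled bin
#' counts, summarises reliability; its slope uncertainty comes from a
#' pair-resampling bootstrap.
#'
#' @param prob,outcome pooled forecasts and binary outcomes.
#' @param weight case weights (e.g. country cropland area; default 1).
#' @param n_bins number of probability bins (default 5).
#' @param R,level bootstrap replicates and interval coverage (default 1000,
#'   0.75).
#' @param seed optional RNG seed for the bootstrap.
#' @return list with the `bins` table, `slope`, `slope_ci`, the pooled
#'   climatological frequency `climatology`, and the no-skill line intercept
#'   `no_skill` (midway between climatology and the diagonal, the boundary of
#'   the positive-Brier-skill region).
#' @export
reliability_diagram <- function(prob, outcome, weight = rep(1, length(prob)),
                                n_bins = 5, R = 1000, level = 0.75,
                                seed = NULL) {
  stopifnot(length(prob) == length(outcome), length(prob) == length(weight))
  bins <- reliability_bins(prob, outcome, weight, n_bins)
  slope <- reliability_slope(bins)
  clim <- sum(weight * outcome) / sum(weight)
  slope_ci <- c(NA_real_, NA_real_)
  if (is.finite(slope)) {
    ci <- bootstrap_ci(length(prob), function(idx) {
      reliability_slope(reliability_bins(prob[idx], outcome[idx], weight[idx],
                                         n_bins))
    }, R = R, level = level, seed = seed)
    slope_ci <- c(ci$lower, ci$upper)
  }
  list(bins = bins, slope = slope,
       slope_ci = slope_ci, level = level,
       climatology = clim, no_skill = clim / 2)
}

#' ROC curve and ROC skill score
#'
#' Sweeps a probability decision threshold (default steps of 20%) through the
#' forecasts, computing the hit rate `j/(j+l)` and false-alarm rate
#' `k/(k+m)`; the curve is closed at (0,0) and (1,1), the area computed by
#' the trapezoid rule, and `ROCSS = 2*area - 1`.
#'
#' @param prob,outcome pooled forecasts and binary outcomes.
#' @param weight case weights (default 1).
#' @param step probability threshold step (default 0.2).
#' @param R,level bootstrap replicates and interval coverage.
#' @param seed optional RNG seed for the bootstrap.
#' @return list with the `points` table (threshold, hit rate, false-alarm
#'   rate), `area`, `rocss` and `rocss_ci`.
#' @export
roc_and_rocss <- function(prob, outcome, weight = rep(1, length(prob)),
                          step = 0.2, R = 1000, level = 0.75, seed = NULL) {
  if (length(unique(outcome > 0)) < 2) {
    stop("undefined-ROC error: only one outcome class present")
  }
  sweep_rocss <- function(prob, outcome, weight) {
    thr <- seq(step, 1, by = step)
    pts <- t(vapply(thr, function(th) {
      ct <- weighted_contingency(prob, outcome, th, weight)
      c(hit = ct[["j"]] / (ct[["j"]] + ct[["l"]]),
        far = ct[["k"]] / (ct[["k"]] + ct[["m"]]))
    }, numeric(2)))
    x <- c(0, rev(pts[, "far"]), 1)
    y <- c(0, rev(pts[, "hit"]), 1)
    area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    list(points = data.frame(threshold = thr, hit = pts[, "hit"],
                             far = pts[, "far"]),
         area = area, rocss = 2 * area - 1)
  }
  full <- sweep_rocss(prob, outcome, weight)
  ci <- bootstrap_ci(length(prob), function(idx) {
    o <- outcome[idx]
    if (length(unique(o > 0)) < 2) return(NA_real_)
    sweep_rocss(prob[idx], o, weight[idx])$rocss
  }, R = R, level = level, seed = seed)
  c(full, list(rocss_ci = c(ci$lower, ci$upper), level = level))
}

#' Classify maize area under drought, heat or combined stress
#'
#' For each year, countries (restricted upstream to those with significant
#' CSI models) are placed in exclusive categories from their de-trended
#' predictors: drought only (`SPEI* < -1` and `HDD*std < 1`), heat only
#' (`SPEI* > -1` and `HDD*std > 1`) or combined (`SPEI* < -1` and
#' `HDD*std > 1`); the maize production area in each category is summed and
#' divided by the total considered area.
#'
#' @param spei,hdd `[year, country]` matrices of de-trended predictor series.
#' @param areas per-country maize production areas (named or in column
#'   order).
#' @return data frame with per-year fractions `drought_only`, `heat_only`,
#'   `combined`.
#' @export
classify_stress_area <- function(spei, hdd, areas) {
  spei <- as.matrix(spei)
  hdd <- as.matrix(hdd)
  stopifnot(all(dim(spei) == dim(hdd)), ncol(spei) == length(areas))
  total <- sum(areas)
  if (total <= 0) stop("configuration error: zero total area")
  frac <- function(catmat) as.vector(catmat %*% areas) / total
  data.frame(
    year = seq_len(nrow(spei)),
    drought_only = frac(spei < -1 & hdd < 1),
    heat_only = frac(spei > -1 & hdd > 1),
    combined = frac(spei < -1 & hdd > 1)
  )
}
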