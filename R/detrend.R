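# Decadal-trend removal and standardisation.  Yields are de-trended on the
# log scale with linear + quadratic terms; the same polynomial procedure is
# applied to the HDD and SPEI series (identity scale) so that the anomalies
# isolate interannual climate-driven variability.

#' Mann-Kendall trend test
#'
#' Non-parametric monotone-trend test: `S = sum_{i<j} sign(x_j - x_i)`, with
#' the tie-corrected normal approximation for the two-sided p-value.
#'
#' @param x annual values, length >= 8; ties allowed.
#' @return list with `S`, `tau` (= S / (n(n-1)/2)), `varS` and `p`.
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 8) stop("insufficient-data error: Mann-Kendall needs n >= 8")
  if (any(!is.finite(x))) stop("non-finite values in series")
  o <- outer(x, x, "-")           # o[i, j] = x_i - x_j
  S <- sum(sign(-o[upper.tri(o)]))
  ties <- table(x)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (varS <= 0 || S == 0) 0 else (S - sign(S)) / sqrt(varS)
  list(S = S, tau = S / (n * (n - 1) / 2), varS = varS,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Fit a quadratic decadal trend
#'
#' Least-squares fit of the (optionally log-transformed) series on centred
#' year and year squared, with Mann-Kendall diagnostics.  Centring makes the
#' fit invariant to the year origin.
#'
#' @param x annual values (strictly positive when `transform = "log"`).
#' @param years calendar years, same length as `x`; `n >= 5`.
#' @param transform `"identity"` or `"log"`.
#' @return object of class `csi_trendfit`: `coefficients`
#'   (intercept, linear, quadratic on the transformed scale), `years_mean`,
#'   `transform`, residuals and Mann-Kendall statistics (when n >= 8).
#' @export
fit_trend <- function(x, years, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  if (length(x) != length(years)) stop("x and years lengths differ")
  if (length(x) < 5) stop("insufficient-data error: trend fit needs n >= 5")
  z <- if (transform == "log") {
    if (any(x <= 0)) stop("domain error: non-positive value under log transform")
    log(x)
  } else {
    as.numeric(x)
  }
  ym <- mean(years)
  tt <- years - ym
  fit <- stats::lm.fit(cbind(1, tt, tt^2), z)
  mk <- if (length(z) >= 8) mann_kendall(z) else NULL
  structure(list(
    transform = transform,
    coefficients = stats::setNames(fit$coefficients,
                                   c("intercept", "linear", "quadratic")),
    years_mean = ym, residuals = fit$residuals,
    mk_statistic = if (is.null(mk)) NA_real_ else mk$S,
    mk_pvalue = if (is.null(mk)) NA_real_ else mk$p
  ), class = "csi_trendfit")
}

#' @export
predict.csi_trendfit <- function(object, years, ...) {
  tt <- years - object$years_mean
  b <- object$coefficients
  b[["intercept"]] + b[["linear"]] * tt + b[["quadratic"]] * tt^2
}

#' De-trend (and optionally standardise) an annual series
#'
#' Removes the fitted quadratic trend and, when `standardise` is set, divides
#' the residuals by their standard deviation.  Yields and HDD are de-trended
#' and standardised; SPEI is de-trended only, being standardised by
#' construction.
#'
#' @param x annual values.
#' @param years calendar years.
#' @param transform passed to [fit_trend()] when no fit is supplied.
#' @param standardise divide residuals by their sd (default TRUE).
#' @param fit an existing `csi_trendfit` to reuse (e.g. the observation fit
#'   applied to forecast-derived series); fitted from `x` when NULL.
#' @param gate_on_mk if TRUE, the trend is only removed when the Mann-Kendall
#'   test on the (transformed) series is significant at `alpha`; otherwise the
#'   series is merely centred.  Default FALSE: unconditional removal.
#' @param alpha significance level for the Mann-Kendall gate.
#' @return list with `values` (the anomaly series), `fit`, `sd` (residual sd)
#'   and `standardised`.
#' @export
detrend_standardise <- function(x, years, transform = "identity",
                                standardise = TRUE, fit = NULL,
                                gate_on_mk = FALSE, alpha = 0.05) {
  own_fit <- is.null(fit)
  if (own_fit) fit <- fit_trend(x, years, transform)
  z <- if (fit$transform == "log") log(x) else as.numeric(x)
  detrended <- if (gate_on_mk && own_fit &&
                   is.finite(fit$mk_pvalue) && fit$mk_pvalue > alpha) {
    z - mean(z)
  } else {
    z - predict(fit, years)
  }
  s <- stats::sd(detrended)
  if (standardise) {
    if (!is.finite(s) || s < 1e-12) {
      stop("degenerate-series error: zero residual variance")
    }
    detrended <- detrended / s
  }
  list(values = detrended, fit = fit, sd = s, standardised = standardise)
}

# Apply an observation-derived trend fit and scale to a forecast-derived
# series so forecast and observed anomalies live on one scale.
anomaly_from_fit <- function(x, years, fit, sd = 1) {
  z <- if (fit$transform == "log") log(x) else as.numeric(x)
  (z - predict(fit, years)) / sd
}
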