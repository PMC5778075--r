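# The Combined Stress Index model: a bilinear ridge regression of
# standardised yield anomalies on the drought (SPEI) and heat (HDD)
# predictors,
#   Y*std_t = a * SPEI*_t + b * HDD*std_t + eps_t = CSI_t + eps_t,
# with the SPEI aggregation window chosen per country by maximising the
# leave-one-out predictive performance Q^2.

#' Bilinear ridge fit of yield anomalies on SPEI and HDD
#'
#' Minimises `sum(y - a*spei - b*hdd)^2 + lambda*(a^2 + b^2)`, intercept-free
#' on centred/standardised series, via the closed-form 2x2 normal equations.
#' The penalty accounts for the covariance of the two agro-climatic
#' predictors.
#'
#' @param y standardised yield anomalies.
#' @param spei,hdd predictor anomaly series, aligned with `y`.
#' @param lambda ridge penalty, >= 0.
#' @return named coefficients `c(a = , b = )`.
#' @export
ridge_fit <- function(y, spei, hdd, lambda = 0) {
  if (lambda < 0) stop("lambda must be >= 0")
  X <- cbind(spei, hdd)
  if (lambda == 0 &&
      (stats::sd(spei) < 1e-12 || stats::sd(hdd) < 1e-12 ||
       abs(stats::cor(spei, hdd)) > 1 - 1e-12)) {
    stop("singularity error: degenerate predictors with lambda = 0")
  }
  A <- crossprod(X) + diag(lambda, 2)
  b <- solve(A, crossprod(X, y))
  stats::setNames(as.numeric(b), c("a", "b"))
}

# Exact leave-one-out PRESS for a fixed ridge penalty via the hat-matrix
# identity e_i / (1 - h_ii); used to select lambda inside each training fold.
ridge_press <- function(y, X, lambda) {
  Ainv <- solve(crossprod(X) + diag(lambda, 2))
  beta <- Ainv %*% crossprod(X, y)
  h <- rowSums((X %*% Ainv) * X)
  r <- (y - X %*% beta) / (1 - h)
  sum(r^2)
}

choose_lambda <- function(y, X, lambda_grid) {
  press <- vapply(lambda_grid, function(l) ridge_press(y, X, l), numeric(1))
  lambda_grid[which.min(press)]
}

#' Leave-one-out predictive performance Q^2
#'
#' `Q^2 = 1 - sum_t (yhat_t^(-t) - y_t)^2 / sum_t (y_t - y_mean)^2`, where
#' `yhat_t^(-t)` is the prediction for year t from a model calibrated on the
#' remaining years.
#'
#' @param y observed (standardised) yield anomalies.
#' @param yhat leave-one-out predictions.
#' @param y_mean long-term mean used in the denominator (default the full
#'   sample mean of `y`).
#' @return Q^2; 1 for perfect prediction, 0 for the climatology predictor,
#'   negative when worse than climatology.
#' @export
q2_score <- function(y, yhat, y_mean = mean(y)) {
  denom <- sum((y - y_mean)^2)
  if (denom <= 0) stop("degenerate-series error: constant yield series")
  1 - sum((yhat - y)^2) / denom
}

default_lambda_grid <- function() 10^seq(-3, 2, by = 1)

#' Leave-one-out Q^2 of a CSI candidate with nested ridge-penalty selection
#'
#' For each year t the model is refitted on the remaining years - including
#' re-selection of the ridge penalty by an inner leave-one-out PRESS over a
#' log-spaced grid (nested cross-validation, so the penalty choice never sees
#' the held-out year) - and year t is predicted.
#'
#' @param y standardised yield anomalies.
#' @param spei,hdd predictor series aligned with `y`.
#' @param lambda_grid candidate ridge penalties (default `10^(-3:2)`).
#' @return list with `q2`, `n`, the leave-one-out `predictions` and the
#'   per-fold selected `lambdas`.
#' @export
loo_q2 <- function(y, spei, hdd, lambda_grid = default_lambda_grid()) {
  n <- length(y)
  if (n < 10) stop("insufficient-data error: LOO Q^2 needs n >= 10")
  X <- cbind(spei, hdd)
  pred <- numeric(n)
  lambdas <- numeric(n)
  for (t in seq_len(n)) {
    Xt <- X[-t, , drop = FALSE]
    yt <- y[-t]
    l <- choose_lambda(yt, Xt, lambda_grid)
    beta <- solve(crossprod(Xt) + diag(l, 2), crossprod(Xt, yt))
    pred[t] <- X[t, ] %*% beta
    lambdas[t] <- l
  }
  list(q2 = q2_score(y, pred), n = n, predictions = pred, lambdas = lambdas)
}

#' Calibrate a country CSI model with SPEI-window optimisation
#'
#' Evaluates the leave-one-out Q^2 for each SPEI aggregation candidate
#' (timescale x ending month), selects the maximiser (ties broken towards the
#' smaller timescale, then the earlier month), and refits the final (a, b) on
#' all years with the full-sample PRESS-selected penalty.
#'
#' @param y standardised yield anomalies.
#' @param spei_candidates named list of candidate lists, each with `values`,
#'   `k` and `ending_month`; supplied in (k, month)-lexicographic order.
#' @param hdd standardised HDD anomaly series.
#' @param lambda_grid ridge penalty grid.
#' @param country optional id stored on the model.
#' @return object of class `csi_model`: coefficients `a`, `b`, `lambda`, the
#'   chosen window (`k`, `ending_month`), `q2`, leave-one-out predictions and
#'   the training series.
#' @export
optimise_spei_choice <- function(y, spei_candidates, hdd,
                                 lambda_grid = default_lambda_grid(),
                                 country = NA_character_) {
  stopifnot(length(spei_candidates) >= 1)
  ord <- order(vapply(spei_candidates, `[[`, numeric(1), "k"),
               vapply(spei_candidates, `[[`, numeric(1), "ending_month"))
  spei_candidates <- spei_candidates[ord]
  res <- lapply(spei_candidates, function(cand) {
    loo_q2(y, cand$values, hdd, lambda_grid)
  })
  q2s <- vapply(res, `[[`, numeric(1), "q2")
  best <- which.max(q2s)              # first maximum = lexicographic tie-break
  cand <- spei_candidates[[best]]
  lambda <- choose_lambda(y, cbind(cand$values, hdd), lambda_grid)
  coef <- ridge_fit(y, cand$values, hdd, lambda)
  structure(list(
    country = country, a = coef[["a"]], b = coef[["b"]],
    ridge_lambda = lambda, k = cand$k, ending_month = cand$ending_month,
    q2 = q2s[[best]], q2_all = q2s,
    loo_predictions = res[[best]]$predictions,
    y = y, spei = cand$values, hdd = hdd
  ), class = "csi_model")
}

#' Predict the Combined Stress Index
#'
#' `CSI = a * SPEI* + b * HDD*std`, an estimate of the standardised yield
#' anomaly (no residual term).
#'
#' @param model a `csi_model`.
#' @param spei,hdd predictor anomaly values (vectors or arrays).
#' @return CSI values, same shape as the inputs.
#' @export
predict_csi <- function(model, spei, hdd) {
  stopifnot(inherits(model, "csi_model"))
  model$a * spei + model$b * hdd
}

#' @export
print.csi_model <- function(x, ...) {
  cat(sprintf("CSI model%s: a = %.3f (SPEI%d, ending month %d), b = %.3f, lambda = %g, Q2 = %.3f\n",
              if (is.na(x$country)) "" else paste0(" [", x$country, "]"),
              x$a, x$k, x$ending_month, x$b, x$ridge_lambda, x$q2))
  invisible(x)
}

#' Permutation significance test for a model's Q^2
#'
#' Re-evaluates the leave-one-out Q^2 (with nested penalty selection, at the
#' model's chosen SPEI window) on year-permuted yield series; the observed
#' Q^2 is significant when positive and above the `1 - alpha` quantile of the
#' permutation null.
#'
#' @param model a `csi_model`.
#' @param B number of permutations (default 500; a warning below 100).
#' @param alpha significance level (default 0.05).
#' @param seed optional RNG seed for the permutations.
#' @return list with `significant`, `p` (permutation p-value), the null
#'   quantile and the null sample.
#' @export
significance_test <- function(model, B = 500, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(model, "csi_model"))
  if (B < 100) warning("configuration warning: B < 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  null_q2 <- vapply(seq_len(B), function(i) {
    loo_q2(sample(model$y), model$spei, model$hdd)$q2
  }, numeric(1))
  crit <- stats::quantile(null_q2, 1 - alpha, names = FALSE)
  list(significant = model$q2 > 0 && model$q2 > crit,
       p = (1 + sum(null_q2 >= model$q2)) / (B + 1),
       critical = crit, null = null_q2)
}
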