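# Probabilistic verification: ETS, contingency tables, event probabilities,
# reliability, ROC/ROCSS, bootstrap intervals and the stress-area
# classification.

test_that("the Equitable Threat Score evaluates its closed form", {
  expect_equal(ets(8, 0, 0, 22), 1)                 # perfect forecast
  expect_equal(ets(5, 5, 5, 5), 0)                  # j_r = 5 exactly
  expect_equal(ets(2, 1, 1, 6), 1.1 / 3.1)          # j_r = 0.9
  expect_true(is.na(ets(0, 0, 0, 10)))              # all correct negatives
  # invariant under joint scaling of the table
  expect_equal(ets(2, 1, 1, 6), ets(6, 3, 3, 18), tolerance = 1e-12)
  expect_error(ets(-1, 0, 0, 2), "nonnegative")
})

test_that("contingency tables count forecast events with the >= rule", {
  ct <- contingency_from_probs(c(0.6, 0.5), c(1, 1), member_fraction = 0.6)
  expect_equal(unname(ct), c(1, 0, 1, 0))
  ct0 <- contingency_from_probs(c(0.1, 0.9, 0), c(1, 0, 1), member_fraction = 0)
  expect_equal(ct0[["l"]] + ct0[["m"]], 0)          # every year forecast
  # brute-force year-by-year tally on a random 30-year case
  set.seed(12)
  prob <- sample(0:10, 30, replace = TRUE) / 10
  outcome <- rbinom(30, 1, 0.3)
  j <- k <- l <- m <- 0
  for (t in 1:30) {
    f <- prob[t] >= 0.5
    if (f && outcome[t] == 1) j <- j + 1
    if (f && outcome[t] == 0) k <- k + 1
    if (!f && outcome[t] == 1) l <- l + 1
    if (!f && outcome[t] == 0) m <- m + 1
  }
  expect_equal(unname(contingency_from_probs(prob, outcome, 0.5)),
               c(j, k, l, m))
})

test_that("event probabilities are member fractions against the 25th percentile", {
  member_csi <- rbind(rep(-2, 5), rep(-2, 5), rep(0.5, 5), rep(0.5, 5),
                      rep(-2, 5), rep(0.5, 5), rep(-2, 5), rep(-2, 5),
                      rep(0.5, 5), rep(0.5, 5))
  obs <- c(-1, 0, 1, -2, 3)
  pf <- event_probabilities(member_csi, obs, threshold = -0.5)
  expect_equal(pf$prob, rep(0.5, 5))
  expect_equal(pf$outcome, c(1, 0, 0, 1, 0))
  # a 30-year series has 8 low-yield years under the interpolated quantile
  set.seed(13)
  csi <- rnorm(30)
  thr <- event_threshold(csi)
  expect_equal(sum(csi < thr), 8)
})

test_that("ROC discriminates perfectly separable forecasts and label reversal negates ROCSS", {
  prob <- c(rep(0.9, 10), rep(0.1, 30))
  outcome <- c(rep(1, 10), rep(0, 30))
  r <- roc_and_rocss(prob, outcome, R = 50, seed = 1)
  expect_equal(r$area, 1)
  expect_equal(r$rocss, 1)
  expect_true(all(diff(c(0, rev(r$points$hit), 1)) >= 0))   # monotone sweep
  set.seed(14)
  prob2 <- sample(0:10, 200, replace = TRUE) / 10
  outcome2 <- rbinom(200, 1, 0.3)
  r_fwd <- roc_and_rocss(prob2, outcome2, R = 50, seed = 1)
  r_rev <- roc_and_rocss(prob2, 1 - outcome2, R = 50, seed = 1)
  expect_equal(r_rev$rocss, -r_fwd$rocss, tolerance = 1e-12)
  expect_error(roc_and_rocss(prob2, rep(1, 200), R = 10), "undefined-ROC")
})

test_that("ROCSS of outcome-independent forecasts is near zero", {
  set.seed(15)
  prob <- sample(0:10, 1000, replace = TRUE) / 10
  outcome <- rbinom(1000, 1, 0.25)
  r <- roc_and_rocss(prob, outcome, R = 50, seed = 2)
  expect_lt(abs(r$rocss), 0.1)
})

test_that("reliability bins report weighted frequencies and degenerate cases", {
  # constant outcome zero: observed frequency zero in every populated bin
  set.seed(16)
  prob <- runif(200)
  rel <- reliability_diagram(prob, rep(0, 200), R = 50, seed = 3)
  expect_true(all(rel$bins$observed[rel$bins$weight > 0] == 0))
  # all forecasts at climatology: a single populated bin, no slope
  relc <- suppressWarnings(reliability_diagram(rep(0.25, 100),
                                               rbinom(100, 1, 0.25),
                                               R = 50, seed = 4))
  expect_equal(sum(relc$bins$weight > 0), 1)
  expect_true(is.na(relc$slope))
  # weighting moves the pooled climatological frequency
  rel_w <- reliability_diagram(c(0.1, 0.9), c(0, 1), weight = c(3, 1),
                               R = 50, seed = 5)
  expect_equal(rel_w$climatology, 0.25)
  expect_equal(rel_w$no_skill, 0.125)
})

test_that("a calibrated ensemble has reliability slope near one", {
  set.seed(17)
  prob <- sample(0:10, 5000, replace = TRUE) / 10
  outcome <- rbinom(5000, 1, prob)
  rel <- reliability_diagram(prob, outcome, R = 100, seed = 6)
  expect_gt(rel$slope, 0.9)
  expect_lt(rel$slope, 1.1)
  expect_true(rel$slope_ci[1] <= rel$slope && rel$slope <= rel$slope_ci[2])
})

test_that("bootstrap intervals are seeded percentile intervals", {
  ci <- bootstrap_ci(50, function(idx) 7, R = 100, seed = 1)
  expect_equal(ci$lower, 7)
  expect_equal(ci$upper, 7)
  set.seed(18)
  x <- rnorm(100)
  stat <- function(idx) mean(x[idx])
  ci1 <- bootstrap_ci(100, stat, R = 500, level = 0.75, seed = 9)
  ci2 <- bootstrap_ci(100, stat, R = 500, level = 0.75, seed = 9)
  expect_identical(ci1$values, ci2$values)
  # CLT check: 75% interval width ~ 2 * z_0.875 / sqrt(n)
  widths <- replicate(20, {
    xx <- rnorm(100)
    ci <- bootstrap_ci(100, function(idx) mean(xx[idx]), R = 400)
    ci$upper - ci$lower
  })
  expected <- 2 * qnorm(0.875) / sqrt(100)
  expect_lt(abs(mean(widths) - expected) / expected, 0.2)
  expect_error(bootstrap_ci(10, function(idx) NA_real_, R = 50),
               "bootstrap failure")
})

test_that("correlation skill flags perfect and null relationships", {
  x <- rnorm(30)
  expect_equal(correlation_skill(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(correlation_skill(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(correlation_skill(rep(1, 30), x), "undefined-correlation")
  set.seed(19)
  hits <- replicate(1000, correlation_skill(rnorm(30), rnorm(30))$significant)
  expect_gt(mean(hits), 0.025)
  expect_lt(mean(hits), 0.085)
})

test_that("ensemble CSI is linear in the member indices", {
  m <- structure(list(a = 0.4, b = -0.6, country = "X"), class = "csi_model")
  set.seed(20)
  spei <- matrix(rnorm(50), 10, 5)
  hdd <- matrix(rnorm(50), 10, 5)
  e <- ensemble_csi(spei, hdd, m)
  expect_equal(e$mean, predict_csi(m, colMeans(spei), colMeans(hdd)),
               tolerance = 1e-12)
  one <- ensemble_csi(spei[rep(1, 10), ], hdd[rep(1, 10), ], m)
  expect_equal(one$mean, one$member[1, ], tolerance = 1e-12)
  expect_error(ensemble_csi(spei, hdd[, 1:3], m), "completeness")
})

test_that("stress-area fractions follow the exclusive category rules", {
  areas <- c(1, 2, 3)
  both <- classify_stress_area(matrix(-2, 4, 3), matrix(2, 4, 3), areas)
  expect_true(all(both$combined == 1))
  expect_true(all(both$drought_only == 0) && all(both$heat_only == 0))
  none <- classify_stress_area(matrix(0, 4, 3), matrix(0, 4, 3), areas)
  expect_true(all(none[, -1] == 0))
  # mixed 3-country hand tally: country1 drought-only, country2 combined,
  # country3 unstressed
  spei <- matrix(c(-1.5, -1.5, 0), 1, 3)
  hdd <- matrix(c(0, 1.5, 0), 1, 3)
  fr <- classify_stress_area(spei, hdd, areas)
  expect_equal(fr$drought_only, 1 / 6)
  expect_equal(fr$combined, 2 / 6)
  expect_equal(fr$heat_only, 0)
  # categories exclusive: fractions sum to at most 1
  set.seed(21)
  s <- matrix(rnorm(60), 20, 3)
  h <- matrix(rnorm(60), 20, 3)
  fr2 <- classify_stress_area(s, h, areas)
  expect_true(all(rowSums(fr2[, -1]) <= 1 + 1e-12))
  expect_true(all(fr2[, -1] >= 0 & fr2[, -1] <= 1))
  expect_error(classify_stress_area(s, h, c(0, 0, 0)), "zero total area")
})
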