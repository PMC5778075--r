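# Heat degree days, Thornthwaite PET, SPEI and crop-weighted aggregation.

test_that("heat degree days sum the daily exceedances over the threshold", {
  expect_equal(compute_hdd_cell(c(31, 29, 33), t_thr = 30), 4)
  expect_equal(compute_hdd_cell(rep(25, 92)), 0)
  # translation covariance: all days above threshold, +delta adds N*delta
  x <- runif(92, 31, 40)
  expect_equal(compute_hdd_cell(x + 0.5), compute_hdd_cell(x) + 92 * 0.5)
  # monotone under pointwise increase
  y <- x + runif(92, 0, 2)
  expect_gte(compute_hdd_cell(y), compute_hdd_cell(x))
})

test_that("heat degree days enforce the missing-data policy", {
  x <- c(rep(31, 80), rep(NA, 12))       # 13% missing
  expect_error(compute_hdd_cell(x), "data-completeness")
  expect_true(is.na(compute_hdd_cell(x, on_missing = "na")))
  x2 <- c(rep(31, 90), NA, NA)           # ~2% missing: tolerated
  expect_equal(compute_hdd_cell(x2), 90)
})

test_that("hdd matches a brute-force daily loop", {
  set.seed(42)
  for (i in 1:25) {
    tmax <- rnorm(92, 28, 3)
    thr <- runif(1, 28, 32)
    acc <- 0
    for (d in seq_along(tmax)) {
      if (tmax[d] > thr) acc <- acc + (tmax[d] - thr)
    }
    expect_equal(compute_hdd_cell(tmax, thr), acc, tolerance = 1e-12)
  }
})

test_that("Thornthwaite PET obeys the cold cutoff and daylight geometry", {
  tm <- c(-5, -1, 0, 2, 8, 14, 19, 18, 12, 7, 2, -2)
  pet <- compute_pet(tm, lat = 50)
  expect_true(all(pet[tm <= 0] == 0))
  expect_true(all(pet >= 0))
  # equator: identical daylight correction, so per-day PET is flat for a
  # uniform temperature
  pet_eq <- compute_pet(rep(20, 12), lat = 0)
  md <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  expect_equal(max(pet_eq / md) - min(pet_eq / md), 0, tolerance = 1e-12)
  expect_error(compute_pet(rep(10, 12), lat = 95), "domain error")
})

test_that("Thornthwaite PET matches an independent step-by-step evaluation", {
  tm <- c(0.5, 2, 6, 11, 16, 20, 23, 22, 17, 11, 5, 1)
  lat <- 45
  # independent evaluation of the published formulation, month by month
  I <- 0
  for (m in 1:12) if (tm[m] > 0) I <- I + (tm[m] / 5)^1.514
  a <- 675e-9 * I^3 - 771e-7 * I^2 + 1792e-5 * I + 0.49239
  md <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  expected <- numeric(12)
  for (m in 1:12) {
    if (tm[m] <= 0) next
    J <- sum(md[seq_len(m)]) - md[m] / 2
    delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
    cosw <- -tan(lat * pi / 180) * tan(delta)
    N <- 24 / pi * acos(min(1, max(-1, cosw)))
    expected[m] <- 16 * (N / 12) * (md[m] / 30) * (10 * tm[m] / I)^a
  }
  expect_equal(compute_pet(tm, lat), expected, tolerance = 1e-10)
})

test_that("SPEI is zero at the fitted median and monotone in the balance", {
  set.seed(7)
  d <- rnorm(40, -30, 15)
  fit <- spei_fit(d)
  expect_identical(fit$type, "loglogistic")
  d_med <- fit$gamma + fit$alpha        # F = 0.5 at gamma + alpha
  expect_equal(spei_transform(d_med, fit), 0, tolerance = 1e-12)
  grid <- seq(min(d), max(d), length.out = 50)
  expect_true(all(diff(spei_transform(grid, fit)) > 0))
})

test_that("the PWM fit recovers a known log-logistic distribution", {
  set.seed(123)
  alpha <- 30; beta <- 4; gam <- -80
  u <- runif(10000)
  x <- gam + alpha * (u / (1 - u))^(1 / beta)
  fit <- spei_fit(x)
  expect_identical(fit$type, "loglogistic")
  qll <- function(p, a, b, g) g + a * (p / (1 - p))^(1 / b)
  for (p in c(0.1, 0.5, 0.9)) {
    est <- qll(p, fit$alpha, fit$beta, fit$gamma)
    expect_equal(est, qll(p, alpha, beta, gam), tolerance = 0.02 * abs(qll(p, alpha, beta, gam)))
  }
})

test_that("compute_spei validates its window and reference period", {
  ny <- 25
  pr <- matrix(60, ny, 12)
  pet <- matrix(50, ny, 12)
  expect_error(compute_spei(pr, pet, k = 4, ending_month = 7), "k must")
  expect_error(compute_spei(pr, pet, k = 2, ending_month = 5), "ending_month")
  expect_error(compute_spei(pr[1:10, ], pet[1:10, ], k = 1, ending_month = 7),
               "insufficient-data")
})

test_that("reference-period SPEI is approximately standard normal", {
  w <- small_world()
  sg <- climate_spei(w$clim, k = 2, ending_month = 7)
  mus <- colMeans(sg$values)
  sds <- apply(sg$values, 2, sd)
  expect_true(all(abs(mus) < 0.1))
  expect_true(all(abs(sds - 1) < 0.15))
})

test_that("country aggregation is an exact crop-area-weighted mean", {
  mask <- make_mask(c(1, 1), c("A", "A"))
  expect_equal(aggregate_to_country(matrix(c(2, 4), 1), mask, "A"), 3)
  # uniform field returns the field value
  mask4 <- make_mask(runif(4), rep("A", 4))
  expect_equal(aggregate_to_country(matrix(7, 3, 4), mask4, "A"), rep(7, 3))
  # brute-force dot product oracle on a random 10-cell case
  set.seed(11)
  w <- runif(10)
  mask10 <- make_mask(w, rep("A", 10))
  v <- matrix(rnorm(50), 5, 10)
  expected <- as.vector(v %*% (w / sum(w)))
  expect_equal(aggregate_to_country(v, mask10, "A"), expected, tolerance = 1e-12)
  # linearity
  x <- matrix(rnorm(50), 5, 10)
  y <- matrix(rnorm(50), 5, 10)
  expect_equal(aggregate_to_country(2 * x + 3 * y, mask10, "A"),
               2 * aggregate_to_country(x, mask10, "A") +
                 3 * aggregate_to_country(y, mask10, "A"),
               tolerance = 1e-12)
})

test_that("aggregation drops invalid cell-years and renormalises", {
  mask <- make_mask(c(0.5, 0.5), c("A", "A"))
  v <- matrix(c(2, NA, 4, 6), 2, 2)    # year 2 missing cell 1
  expect_equal(aggregate_to_country(v, mask, "A"), c(3, 6))
  expect_error(aggregate_to_country(matrix(NA_real_, 1, 2), mask, "A"),
               "no valid cells")
  expect_error(aggregate_to_country(v, mask, "B"), "unknown country")
})
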