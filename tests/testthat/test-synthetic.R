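# The synthetic generators: determinism, degenerate limits, the spatial
# correlation structure of the weather model, and the skill mixing of the
# ensemble re-forecasts.

test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- small_config()
  c1 <- generate_climate(cfg)
  c2 <- generate_climate(cfg)
  expect_identical(c1$tmax, c2$tmax)
  expect_identical(c1$precip, c2$precip)
  m1 <- generate_crop_mask(cfg)
  expect_identical(m1, generate_crop_mask(cfg))
  y1 <- generate_yields(c1, m1, cfg)
  y2 <- generate_yields(c2, m1, cfg)
  expect_identical(y1$yields, y2$yields)
  f1 <- generate_forecasts(c1, cfg, start_month = 5)
  f2 <- generate_forecasts(c1, cfg, start_month = 5)
  expect_identical(f1$tmax, f2$tmax)
})

test_that("zero anomaly and noise variances give identical years", {
  cfg <- small_config(anomaly_sd_temp = 0, anomaly_sd_precip = 0,
                      noise_sd_tmax = 0, noise_sd_tmean = 0,
                      noise_sd_precip = 0)
  clim <- generate_climate(cfg)
  hdd <- climate_hdd(clim)
  expect_true(all(abs(sweep(hdd, 2, hdd[1, ])) < 1e-12))
  expect_true(all(abs(sweep(clim$precip, c(2, 3), clim$precip[1, , ])) < 1e-12))
})

test_that("climate config validation rejects bad inputs", {
  expect_error(synth_config(n_years = 10), "n_years")
  expect_error(synth_config(skill_rho = 1.5), "skill_rho")
  expect_error(synth_config(n_lat = 0), "positive")
  expect_error(generate_crop_mask(synth_config(n_lat = 1, n_lon = 2,
                                               n_countries = 3)),
               "more countries than grid cells")
})

test_that("crop mask partitions the grid with per-country weights summing to 1", {
  mask <- generate_crop_mask(small_config())
  sums <- tapply(mask$cells$weight, mask$cells$country, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(mask$cells$weight >= 0))
  # cells partitioned: each cell exactly once, all countries contiguous strips
  expect_identical(sort(mask$cells$cell), seq_len(9L))
  expect_setequal(unique(mask$cells$country), mask$countries)
  by_cty <- split(mask$cells$lon, mask$cells$country)
  ranges <- lapply(by_cty, range)
  for (a in seq_along(ranges)) {
    for (b in seq_along(ranges)) {
      if (a < b) {
        expect_true(ranges[[a]][2] < ranges[[b]][1] ||
                      ranges[[b]][2] < ranges[[a]][1])
      }
    }
  }
})

test_that("interannual correlation of July tmax decays with distance", {
  cfg <- synth_config(n_years = 200, n_lat = 1, n_lon = 6, n_countries = 1,
                      corr_length = 2, seed = 5)
  clim <- generate_climate(cfg)
  july <- which(month_of_doy == 7)
  jt <- apply(clim$tmax[, july, ], c(1, 3), mean)   # [year, cell]
  r_adj <- mean(sapply(1:5, function(i) cor(jt[, i], jt[, i + 1])))
  r_far <- cor(jt[, 1], jt[, 6])
  expect_gt(r_adj, r_far)
})

test_that("yields carry the configured climate signal and trend", {
  w <- small_world()
  yd <- w$yields
  expect_setequal(unique(yd$yields$country), w$mask$countries)
  expect_true(all(yd$yields$yield > 0))
  # noise-free, trendless limit: standardised log-yield anomalies are an
  # exact linear function of the two indices
  cfg0 <- small_config(noise_sd = 0, trend_coeffs = c(0, 0))
  clim0 <- generate_climate(cfg0)
  mask0 <- generate_crop_mask(cfg0)
  y0 <- generate_yields(clim0, mask0, cfg0)
  tr <- y0$truth$countries$C1
  ly <- log(y0$yields$yield[y0$yields$country == "C1"])
  fit <- lm(ly ~ tr$spei_star + tr$hdd_star)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("perfect-skill undistorted forecasts reproduce the observed fields", {
  w <- small_world()
  fc <- generate_forecasts(w$clim, w$cfg, start_month = 5, skill_rho = 1,
                           bias_temp = 0, bias_precip = 0, dispersion = 1)
  for (mem in 1:3) {
    expect_equal(fc$tmax[mem, , , ], w$clim$tmax[, fc$wdoys, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(fc$precip[mem, , , ], w$clim$precip[, fc$months, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("ensemble-mean skill is near zero without signal and grows with skill_rho", {
  cfg <- synth_config(n_years = 200, n_lat = 2, n_lon = 2, n_countries = 1,
                      n_members = 10, seed = 31)
  clim <- generate_climate(cfg)
  july <- which(month_of_doy == 7)
  truth <- apply(clim$tmax[, july, ], 1, mean)
  cors <- sapply(c(0, 0.4, 0.8, 1), function(rho) {
    fc <- generate_forecasts(clim, cfg, start_month = 5, skill_rho = rho,
                             bias_temp = 0, bias_precip = 0, dispersion = 1)
    jd <- which(month_of_doy[fc$wdoys] == 7)
    memj <- apply(fc$tmax[, , jd, , drop = FALSE], c(1, 2), mean)
    cor(colMeans(memj), truth)
  })
  expect_lt(abs(cors[1]), 0.2)
  expect_true(all(diff(cors) >= 0))
  expect_equal(cors[4], 1, tolerance = 1e-10)
  # noise averaging: ensemble mean beats a single member at rho = 0.8
  fc <- generate_forecasts(clim, cfg, start_month = 5, skill_rho = 0.8,
                           bias_temp = 0, bias_precip = 0, dispersion = 1)
  jd <- which(month_of_doy[fc$wdoys] == 7)
  memj <- apply(fc$tmax[, , jd, , drop = FALSE], c(1, 2), mean)
  r_members <- sapply(1:10, function(mm) cor(memj[mm, ], truth))
  expect_gt(cor(colMeans(memj), truth), max(r_members))
})

test_that("undistorted member climatology matches the observed one", {
  cfg <- synth_config(n_years = 60, n_lat = 2, n_lon = 2, n_countries = 1,
                      seed = 77)
  clim <- generate_climate(cfg)
  fc <- generate_forecasts(clim, cfg, start_month = 6, skill_rho = 0.5,
                           bias_temp = 0, bias_precip = 0, dispersion = 1)
  m <- match(7, fc$months)
  obs <- as.vector(clim$tmean[, 7, ])
  mod <- as.vector(fc$tmean[, , m, ])
  expect_equal(mean(mod), mean(obs), tolerance = 0.15)
  expect_equal(sd(mod), sd(obs), tolerance = 0.15)
})
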