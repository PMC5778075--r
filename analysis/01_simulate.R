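#!/usr/bin/env Rscript
# Step 1: generate the synthetic study world.
#
# A 30-year, 6x6-degree grid split into 4 countries: daily maximum
# temperature, monthly mean temperature and monthly precipitation with
# spatially correlated hot-dry coupled anomalies; harvested-maize-area
# weights per country; national yields whose log-scale signal is
# 0.4 * SPEI2 (ending July) - 0.6 * HDD, plus a quadratic technology trend
# and noise.  The ground truth is stored so later steps can be compared
# against it.

suppressPackageStartupMessages(library(csiforecast))

dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = 2026L)
climate <- generate_climate(cfg)
mask <- generate_crop_mask(cfg)
yields <- generate_yields(climate, mask, cfg)

write_yields_csv(yields$yields, "results/yields.csv")
# crop-weighted national monthly climate (the full gridded fields are
# regenerated from the seed on demand)
monthly <- do.call(rbind, lapply(mask$countries, function(cty) {
  data.frame(country = cty,
             year = rep(climate$years, 12),
             month = rep(1:12, each = cfg$n_years),
             tmean = round(as.vector(sapply(1:12, function(m)
               aggregate_to_country(climate$tmean[, m, ], mask, cty))), 2),
             precip = round(as.vector(sapply(1:12, function(m)
               aggregate_to_country(climate$precip[, m, ], mask, cty))), 2))
}))
utils::write.csv(monthly, "results/climate_country_monthly.csv",
                 row.names = FALSE)
utils::write.csv(mask$cells, "results/crop_mask.csv", row.names = FALSE)
jsonlite::write_json(
  list(coeffs = as.list(yields$truth$coeffs),
       trend = as.list(yields$truth$trend),
       spei_window = list(k = yields$truth$k,
                          ending_month = yields$truth$ending_month),
       noise_sd = yields$truth$noise_sd,
       seed = cfg$seed),
  "results/truth.json", auto_unbox = TRUE, digits = NA)

yr <- range(yields$yields$yield)
cat(sprintf("Simulated %d countries x %d years on a %dx%d grid.\n",
            cfg$n_countries, cfg$n_years, cfg$n_lat, cfg$n_lon))
cat(sprintf("Yields span %.2f-%.2f t/ha; generating signal: %.1f*SPEI%d(m%d) %+.1f*HDD.\n",
            yr[1], yr[2], yields$truth$coeffs[["spei"]], yields$truth$k,
            yields$truth$ending_month, yields$truth$coeffs[["hdd"]]))
cat("Wrote results/yields.csv, climate_country_monthly.csv, crop_mask.csv, truth.json\n")
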