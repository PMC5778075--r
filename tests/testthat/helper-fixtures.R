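# Shared fixtures.  Everything is generated in code; the heavier objects are
# built once per test session and cached.

# aliases for internals exercised directly by tests
month_of_doy <- rep(1:12, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
climate_hdd <- csiforecast:::climate_hdd
climate_spei <- csiforecast:::climate_spei
spei_fit <- csiforecast:::spei_fit
spei_transform <- csiforecast:::spei_transform

choose_lambda_test <- function(y, spei, hdd) {
  csiforecast:::choose_lambda(y, cbind(spei, hdd),
                              csiforecast:::default_lambda_grid())
}

small_config <- function(...) {
  synth_config(n_lat = 3, n_lon = 3, n_countries = 2, seed = 99L, ...)
}

# hand-built crop mask over a given weight layout (cells in order)
make_mask <- function(weights, countries) {
  raw <- weights
  norm <- stats::ave(weights, countries, FUN = function(w) w / sum(w))
  area <- tapply(raw, countries, sum)
  structure(list(
    cells = data.frame(cell = seq_along(weights), lat = 0, lon = 0,
                       country = countries, weight = norm, raw_area = raw,
                       stringsAsFactors = FALSE),
    country_area = area[order(names(area))],
    countries = sort(unique(countries))
  ), class = "csi_cropmask")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small observed world shared by several test files
small_world <- function() {
  cached("small_world", {
    cfg <- small_config()
    clim <- generate_climate(cfg)
    mask <- generate_crop_mask(cfg)
    yields <- generate_yields(clim, mask, cfg)
    list(cfg = cfg, clim = clim, mask = mask, yields = yields)
  })
}

# calibration over the small world with a strong signal (used by pipeline and
# verification tests)
strong_world <- function() {
  cached("strong_world", {
    cfg <- small_config(yield_coeffs = c(spei = 0.7, hdd = -0.5),
                        noise_sd = 0.25)
    clim <- generate_climate(cfg)
    mask <- generate_crop_mask(cfg)
    yields <- generate_yields(clim, mask, cfg)
    cal <- calibrate_csi(clim, mask, yields$yields, B = 199, seed = 11L)
    list(cfg = cfg, clim = clim, mask = mask, yields = yields, cal = cal)
  })
}
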