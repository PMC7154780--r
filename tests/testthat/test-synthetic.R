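test_that("noise-free climate is an exact lapse-rate sinusoid", {
  cfg <- climate_config(t_year_sd = 0, t_month_sd = 0, prcp_cv = 0,
                        srad_sd = 0)
  low <- generate_climate_series(list(elevation = 0), cfg, 1990:1991, 1)
  high <- generate_climate_series(list(elevation = 2000), cfg, 1990:1991, 1)
  jan_low <- low$tmin[low$month == 1][1]
  jan_high <- high$tmin[high$month == 1][1]
  expect_equal(jan_low - jan_high, cfg$lapse_rate * 2)
  # exact seasonal cosine at sea level
  expect_equal(low$tmin + cfg$dtr / 2,
               cfg$t_mean_sl + cfg$t_amp * cos(2 * pi * (low$month - 7) / 12))
  expect_true(all(low$tmin <= low$tmax))
  expect_true(all(low$prcp >= 0))
  nd <- days_in_month(low$year, low$month)
  expect_true(all(low$frost_days >= 0 & low$frost_days <= nd))
})

test_that("an injected warm-dry year is warmer and drier than climatology", {
  ex <- data.frame(year = 2003, type = "warm_dry", z_t = 2.5, z_p = -2.5)
  cfg <- climate_config(extreme_years = ex)
  cli <- generate_climate_series(list(elevation = 800), cfg, 1991:2018, 7)
  t_yr <- tapply((cli$tmin + cli$tmax) / 2, cli$year, mean)
  p_yr <- tapply(cli$prcp, cli$year, sum)
  others <- names(t_yr) != "2003"
  expect_gt(t_yr[["2003"]], mean(t_yr[others]))
  expect_lt(p_yr[["2003"]], mean(p_yr[others]))
})

test_that("climate generation is bit-reproducible per seed", {
  cfg <- climate_config()
  a <- generate_climate_series(list(elevation = 1200), cfg, 1980:1999, 5)
  b <- generate_climate_series(list(elevation = 1200), cfg, 1980:1999, 5)
  expect_identical(a, b)
  c2 <- generate_climate_series(list(elevation = 1200), cfg, 1980:1999, 6)
  expect_false(identical(a, c2))
})

test_that("network schedules follow their monitoring-style conventions", {
  cfg <- network_config(n_plots = 30)
  net <- generate_monitoring_network(cfg, seed = 12)
  expect_length(net, 30)
  for (pl in net) {
    expect_gte(length(pl$visit_years), 2) # plot-selection criterion
    if (is.null(pl$management)) next
    if (pl$network == "EFM") {
      expect_true(all(pl$management$year %in% pl$visit_years))
    } else if (pl$network == "NFI") {
      for (yr in pl$management$year) {
        expect_false(yr %in% pl$visit_years)
        expect_true(yr > min(pl$visit_years) & yr < max(pl$visit_years))
      }
    }
  }
  expect_true(any(vapply(net, function(p) p$network == "LWF", logical(1))))
})

test_that("the full-network preset reproduces the monitoring campaign size", {
  # 237 spruce + 34 beech plots
  net_pa <- generate_monitoring_network(
    network_config(n_plots = 237, species = "picea"), seed = 1)
  net_fs <- generate_monitoring_network(
    network_config(n_plots = 34, species = "fagus"), seed = 2)
  expect_length(net_pa, 237)
  expect_length(net_fs, 34)
})

test_that("zero-noise observations equal the simulator's truth", {
  ds <- fixture_dataset(n_plots = 4, noise_rel = 0)
  expect_equal(ds$data$observations$value, ds$data$truth$value)
})

test_that("only intensive plots observe LAI and GPP", {
  ds <- fixture_dataset(n_plots = 8)
  obs <- ds$data$observations
  gpp_nets <- unique(obs$network[obs$variable == "gpp"])
  expect_true(all(gpp_nets == "LWF"))
  lai_nets <- unique(obs$network[obs$variable == "lai"])
  expect_true(all(lai_nets == "LWF"))
  nfi <- obs[obs$network == "NFI", ]
  expect_setequal(unique(nfi$variable),
                  c("stem_biomass", "foliage_biomass", "root_biomass",
                    "n_trees", "dbh", "basal_area"))
})

test_that("observation noise is consistent with its Student-t model", {
  ds <- fixture_dataset(n_plots = 25, seed = 77)
  obs <- ds$data$observations
  truth <- ds$data$truth
  z <- (obs$value - truth$value) / ds$data$noise_scales[obs$variable]
  z <- z[obs$value > 0] # drop zero-clipped rows
  ks <- suppressWarnings(
    stats::ks.test(z, function(q) stats::pt(q, df = ds$config$noise_df))
  )
  expect_gt(ks$p.value, 0.01)
  # and clearly heavier-tailed than a unit Gaussian of the same scale
  expect_gt(max(abs(z)), 3.5)
})

test_that("observation generation is reproducible and respects invariants", {
  ds1 <- fixture_dataset(n_plots = 4, seed = 9)
  ds2 <- fixture_dataset(n_plots = 4, seed = 9)
  expect_identical(ds1$data$observations, ds2$data$observations)
  expect_true(all(ds1$data$observations$value >= 0))
  expect_true(all(ds1$data$observations$variable %in%
                    observation_variables()))
})

test_that("the habitat grid masks by elevation band and pairs cell seeds", {
  grid <- generate_country_grid(200, habitat_range = c(400, 2000), seed = 3)
  expect_true(all(grid$elevation[grid$habitat] >= 400 &
                    grid$elevation[grid$habitat] <= 2000))
  expect_true(all(!grid$habitat | grid$elevation <= 2000))
  # same seed and elevation: identical climate
  site <- list(elevation = 1000)
  a <- generate_climate_series(site, climate_config(), 1961:1990, 42)
  b <- generate_climate_series(site, climate_config(), 1961:1990, 42)
  expect_identical(a, b)
  # full-scale preset matches the spruce grid size
  big <- generate_country_grid(10100, seed = 4)
  expect_gte(nrow(big), 10100)
})

test_that("observation tables round-trip through the CSV dialect", {
  ds <- fixture_dataset(n_plots = 3)
  path <- tempfile(fileext = ".csv")
  write_observation_csv(ds$data$observations, path)
  back <- read_observation_csv(path)
  expect_equal(back$value, ds$data$observations$value)
  expect_equal(back$year, ds$data$observations$year)
  unlink(path)
})
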