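ref_cfg <- function() climate_config(t_year_sd = 0.4)

test_that("spin-up reaches age 40 near the target stocking, deterministically", {
  p <- default_parameters("picea")
  site <- fixture_site(elevation = 900)
  cli <- generate_climate_series(site, ref_cfg(), 1961:1990, seed = 21)
  cy <- climatological_year(cli)
  spin1 <- spin_up_stand(site, cy, p)
  spin2 <- spin_up_stand(site, cy, p)
  expect_identical(spin1, spin2)
  expect_equal(spin1$age, 40, tolerance = 1e-9)
  expect_gt(spin1$n_trees, 850)
  expect_lt(spin1$n_trees, 1300)
  # stocking after the age-35 thinning is at most the age-20 residual
  expect_lte(spin1$n_trees, 2400)
})

test_that("scenario periods window ages 41-70 and aggregate annually", {
  p <- default_parameters("picea")
  site <- fixture_site(elevation = 900)
  cli <- generate_climate_series(site, ref_cfg(), 1961:1990, seed = 21)
  cy <- climatological_year(cli)
  spin <- spin_up_stand(site, cy, p)
  res <- run_scenario_period(site, cli, spin, p)
  expect_equal(nrow(res$annual), 30)
  expect_equal(res$mean_npp_c, mean(res$annual$npp_c))
  # independent aggregation check against the monthly table
  out <- run_simulation(site, cli, p, spin)
  npp_1961 <- sum(out$npp[out$year == 1961]) * 0.5
  expect_equal(res$annual$npp_c[1], npp_1961)
  # ages covered are strictly above 40
  expect_true(all(out$age > 40))
  expect_error(run_scenario_period(site, cli[1:120, ], spin, p),
               "28 years")
})

test_that("a null scenario yields an exactly zero anomaly grid", {
  p <- default_parameters("picea")
  site <- fixture_site(elevation = 900)
  cli <- generate_climate_series(site, ref_cfg(), 1961:1990, seed = 21)
  cy <- climatological_year(cli)
  spin <- spin_up_stand(site, cy, p)
  ref <- run_scenario_period(site, cli, spin, p)
  scn <- run_scenario_period(site, cli, spin, p) # identical forcing
  anom <- 100 * (scn$annual$npp_c - ref$mean_npp_c) / ref$mean_npp_c -
    100 * (ref$annual$npp_c - ref$mean_npp_c) / ref$mean_npp_c
  expect_identical(scn$annual$npp_c, ref$annual$npp_c)
  expect_equal(anom, rep(0, 30))
})

fake_results <- function(npp_ref, annual_scn, elevation,
                         scn_years = 2001:2003) {
  structure(
    list(
      cells = data.frame(cell_id = seq_along(npp_ref),
                         elevation = elevation, npp_ref = npp_ref,
                         npp_scn = rowMeans(annual_scn)),
      annual_scn = annual_scn, scn_years = scn_years,
      excluded = integer(0)
    ),
    class = "regional_result"
  )
}

test_that("anomaly fractions count strictly-below cells only", {
  npp_ref <- rep(4, 4)
  # year 1: all cells exactly at the -25% threshold; year 2: one below
  annual <- cbind(rep(3, 4), c(2, 4, 4, 4), rep(4, 4))
  res <- fake_results(npp_ref, annual, elevation = c(500, 900, 1300, 1700))
  am <- anomaly_map(res, years = 2001:2003)
  expect_equal(unname(am$affected_fraction[["2001"]]), 0) # ties excluded
  expect_equal(unname(am$affected_fraction[["2002"]]), 25)
  expect_equal(unname(am$affected_fraction[["2003"]]), 0)
  expect_equal(am$anomalies[["2001"]], rep(-25, 4))
  # brute-force filter oracle
  anom2 <- 100 * (annual[, 2] - npp_ref) / npp_ref
  expect_equal(unname(am$affected_fraction[["2002"]]),
               100 * sum(anom2 < -25) / 4)
})

test_that("affected fractions are invariant to cell ordering", {
  set.seed(15)
  npp_ref <- runif(20, 2, 6)
  annual <- matrix(runif(60, 1, 6), 20, 3)
  elev <- runif(20, 400, 2000)
  res <- fake_results(npp_ref, annual, elev)
  perm <- sample(20)
  res_p <- fake_results(npp_ref[perm], annual[perm, , drop = FALSE],
                        elev[perm])
  expect_equal(anomaly_map(res, 2001:2003)$affected_fraction,
               anomaly_map(res_p, 2001:2003)$affected_fraction)
})

test_that("elevation slope recovers a planted linear gradient", {
  elev <- seq(400, 2000, length.out = 30)
  npp <- 6 - 2 * elev / 1000
  res <- fake_results(npp, cbind(npp, npp, npp), elev)
  sl <- suppressWarnings(elevation_gradient_slope(res))
  expect_equal(sl$slope, -2, tolerance = 1e-10)
  expect_lt(sl$se, 1e-10)
  # invariant under adding a constant
  res2 <- fake_results(npp + 3, cbind(npp, npp, npp) + 3, elev)
  expect_equal(suppressWarnings(elevation_gradient_slope(res2))$slope,
               sl$slope)
  # closed-form OLS cross-check with noise
  set.seed(8)
  nppn <- npp + rnorm(30, 0, 0.3)
  res3 <- fake_results(nppn, cbind(nppn, nppn, nppn), elev)
  sl3 <- elevation_gradient_slope(res3)
  x <- elev / 1000
  beta <- sum((x - mean(x)) * (nppn - mean(nppn))) / sum((x - mean(x))^2)
  resid <- nppn - mean(nppn) - beta * (x - mean(x))
  se <- sqrt(sum(resid^2) / 28 / sum((x - mean(x))^2))
  expect_equal(sl3$slope, beta)
  expect_equal(sl3$se, se)
  expect_error(
    elevation_gradient_slope(fake_results(npp[1:3], cbind(npp, npp, npp)[1:3, ],
                                          rep(1000, 3))),
    "constant"
  )
})

test_that("climate years classify into quadrants by standardised anomalies", {
  ref <- list(per_year = data.frame(year = 1:12), t_mean = 12, t_sd = 1,
              p_mean = 600, p_sd = 50)
  mk_year <- function(dt, dp) {
    data.frame(year = 1, month = 1:12, tmin = 12 + dt - 4.5,
               tmax = 12 + dt + 4.5,
               prcp = (600 + dp) / 7 * c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 0, 0),
               srad = 12, frost_days = 0, co2 = 380)
  }
  expect_equal(classify_climate_year(mk_year(2, -100), ref)$label, "warm_dry")
  expect_equal(classify_climate_year(mk_year(-2, -100), ref)$label, "cold_dry")
  expect_equal(classify_climate_year(mk_year(2, 100), ref)$label, "warm_wet")
  expect_equal(classify_climate_year(mk_year(0, 0), ref)$label, "normal")
  expect_error(classify_climate_year(mk_year(0, 0),
                                     list(per_year = data.frame(year = 1:5),
                                          t_mean = 1, t_sd = 1, p_mean = 1,
                                          p_sd = 1)),
               ">= 10 years")
})

test_that("injected extreme years are recovered by the classifier", {
  ex <- data.frame(year = c(2003, 2010),
                   type = c("warm_dry", "cold_dry"),
                   z_t = c(2.5, -2.5), z_p = c(-2.5, -2.5))
  cfg <- climate_config(extreme_years = ex)
  site <- list(elevation = 800)
  ref <- generate_climate_series(site, climate_config(), 1961:1990, 99)
  scn <- generate_climate_series(site, cfg, 1991:2018, 100)
  stats <- growing_season_stats(ref)
  for (r in seq_len(nrow(ex))) {
    yc <- scn[scn$year == ex$year[r], ]
    expect_equal(classify_climate_year(yc, stats)$label, ex$type[r])
  }
})
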