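test_that("VPD proxy vanishes for equal temperature extremes and matches Tetens", {
  expect_equal(compute_vpd(20, 20), 0)
  expect_equal(compute_vpd(-5, -5), 0)
  # independent Tetens evaluation for tmin 10, tmax 25
  es <- function(t) 0.61078 * exp(17.269 * t / (237.3 + t))
  expect_equal(compute_vpd(10, 25), 0.5 * (es(25) - es(10)))
  expect_equal(round(compute_vpd(10, 25), 4), 0.9697)
  expect_error(compute_vpd(10, 5), "tmin")
})

test_that("temperature modifier hits its cardinal anchors", {
  expect_equal(temperature_modifier(15, 0, 15, 30), 1)
  expect_equal(temperature_modifier(0, 0, 15, 30), 0)
  expect_equal(temperature_modifier(30, 0, 15, 30), 0)
  expect_equal(temperature_modifier(-3, 0, 15, 30), 0)
  expect_equal(temperature_modifier(10, 0, 15, 30),
               (10 / 15) * (20 / 15)^(15 / 15))
  expect_error(temperature_modifier(10, 15, 10, 30), "cardinal")
})

test_that("frost modifier is a clamped linear penalty", {
  expect_equal(frost_modifier(0, 30, 0.6), 1)
  expect_equal(frost_modifier(30, 30, 1), 0)
  expect_equal(frost_modifier(10, 30, 0.6), 1 - 0.6 / 3)
  expect_error(frost_modifier(31, 30, 0.5), "frost_days")
})

test_that("VPD modifier decays exponentially in mbar units", {
  expect_equal(vpd_modifier(0, 0.05), 1)
  expect_equal(vpd_modifier(1, 0.05), exp(-0.5))
  expect_lt(vpd_modifier(2, 0.03), vpd_modifier(1, 0.03))
  expect_error(vpd_modifier(-0.1, 0.05), "vpd")
})

test_that("soil water modifier anchors at saturation and half-saturation", {
  expect_equal(soil_water_modifier(150, 150, 0.7, 9), 1)
  expect_equal(soil_water_modifier(150 * (1 - 0.7), 150, 0.7, 9), 0.5)
  expect_equal(soil_water_modifier(0.3 * 150, 150, 0.7, 9), 0.5)
  asw <- seq(0, 150, by = 10)
  f <- soil_water_modifier(asw, 150, 0.7, 9)
  expect_true(all(diff(f) >= 0))
  expect_error(soil_water_modifier(10, 0, 0.7, 9), "asw_max")
})

test_that("fertility modifier interpolates between fn0 and 1", {
  expect_equal(fertility_modifier(1, 0.6, 1), 1)
  expect_equal(fertility_modifier(0, 0.6, 1), 0.6)
  expect_equal(fertility_modifier(0.5, 0.6, 1), 0.8)
  expect_error(fertility_modifier(1.2, 0.6, 1), "fr")
})

test_that("age modifier declines from 1 with a half-point at r_age", {
  expect_equal(age_modifier(0, 300, 4, 0.95), 1)
  expect_equal(age_modifier(300 * 0.95, 300, 4, 0.95), 0.5)
  expect_equal(age_modifier(40, 300, 4, 0.95),
               1 / (1 + ((40 / 300) / 0.95)^4))
})

test_that("CO2 modifiers anchor at 350 and 700 ppm", {
  expect_equal(co2_modifiers(350, 1.4, 0.7),
               c(f_calpha = 1, f_cg = 1))
  m700 <- co2_modifiers(700, 1.4, 0.7)
  expect_equal(m700[["f_calpha"]], 1.4)
  expect_equal(m700[["f_cg"]], 0.7)
  # independent evaluation of the hyperbolae at 420 ppm
  fax <- 1.4 / (2 - 1.4)
  fg0 <- 0.7 / (2 * 0.7 - 1)
  m420 <- co2_modifiers(420, 1.4, 0.7)
  expect_equal(m420[["f_calpha"]], fax * 420 / (350 * (fax - 1) + 420))
  expect_equal(m420[["f_cg"]], fg0 / (1 + (fg0 - 1) * 420 / 350))
  expect_gt(co2_modifiers(500, 1.4, 0.7)[["f_calpha"]], 1)
  expect_lt(co2_modifiers(500, 1.4, 0.7)[["f_cg"]], 1)
})

test_that("all modifiers stay within [0,1] over randomized admissible inputs", {
  set.seed(301)
  for (rep in 1:200) {
    p <- random_admissible_params()
    site <- fixture_site(asw_max = runif(1, 50, 250),
                         fr = runif(1, 0, 1))
    tmean <- runif(1, -15, 30)
    cm <- list(tmin = tmean - 4, tmax = tmean + 4,
               frost_days = round(runif(1, 0, 28)),
               co2 = runif(1, 300, 700))
    mods <- compute_modifiers(cm, runif(1, 0, site$asw_max),
                              runif(1, 0, 200), site, p, 30)
    for (nm in c("f_t", "f_frost", "f_vpd", "f_sw", "f_nutr", "f_age",
                 "phys_mod")) {
      expect_gte(mods[[nm]], 0)
      expect_lte(mods[[nm]], 1)
    }
    expect_gte(mods$f_calpha, 0)
    expect_gte(mods$f_cg, 0)
  }
})

test_that("days_in_month is calendar-true including leap years", {
  expect_equal(days_in_month(2000, 2), 29)
  expect_equal(days_in_month(1900, 2), 28)
  expect_equal(days_in_month(2004, 2), 29)
  expect_equal(days_in_month(2001, c(1, 4, 12)), c(31, 30, 31))
})
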