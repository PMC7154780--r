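test_that("perfect predictions give zero bias and error", {
  obs <- data.frame(plot_id = rep(c("a", "b"), each = 3),
                    variable = "dbh", value = c(10, 12, 14, 20, 22, 24))
  st <- prediction_statistics(obs, obs$value)
  expect_equal(st$median, rep(0, 3))
})

test_that("a constant +10% error yields pBias exactly 10", {
  obs <- data.frame(plot_id = rep(c("a", "b"), each = 3),
                    variable = "stem_biomass",
                    value = c(50, 70, 90, 110, 130, 150))
  st <- prediction_statistics(obs, obs$value * 1.1)
  expect_equal(st$median[st$statistic == "pBias"], 10)
})

test_that("statistics average plot-first, not pooled", {
  # two plots on very different scales; hand-worked expectations
  obs <- data.frame(plot_id = c("a", "a", "b", "b"),
                    variable = "basal_area",
                    value = c(10, 20, 100, 200))
  pred <- c(12, 22, 90, 190)
  st <- prediction_statistics(obs, pred)
  # plot a: pBias 100*4/30, RMSE 2, NRMSE 100*2/15
  # plot b: pBias 100*(-20)/300, RMSE 10, NRMSE 100*10/150
  expect_equal(st$median[st$statistic == "pBias"],
               (100 * 4 / 30 + 100 * (-20) / 300) / 2)
  expect_equal(st$median[st$statistic == "RMSE"], (2 + 10) / 2)
  expect_equal(st$median[st$statistic == "NRMSE"],
               (100 * 2 / 15 + 100 * 10 / 150) / 2)
  # the pooled alternative would differ
  pooled <- 100 * sum(pred - obs$value) / sum(obs$value)
  expect_false(isTRUE(all.equal(st$median[st$statistic == "pBias"], pooled)))
})

test_that("cross-validation splits by plot with the documented tie rule", {
  s10 <- cross_validation_split(paste0("p", 1:10), seed = 5)
  expect_equal(length(s10$calibration), 5)
  expect_equal(length(s10$validation), 5)
  s11 <- cross_validation_split(paste0("p", 1:11), seed = 5)
  expect_equal(length(s11$calibration), 6)
  expect_equal(length(s11$validation), 5)
  expect_length(intersect(s11$calibration, s11$validation), 0)
  expect_identical(cross_validation_split(paste0("p", 1:10), seed = 7),
                   cross_validation_split(paste0("p", 1:10), seed = 7))
  expect_false(identical(cross_validation_split(paste0("p", 1:10), seed = 7),
                         cross_validation_split(paste0("p", 1:10), seed = 8)))
  expect_error(cross_validation_split("p1", 1), "at least 2")
})

test_that("a single-sample ensemble yields zero-width predictive intervals", {
  ds <- fixture_dataset(n_plots = 3)
  ts <- reduced_theta_spec(fixture_priors())
  one <- matrix(ds$theta[ts$name], 1, nrow(ts),
                dimnames = list(NULL, ts$name))
  ens <- structure(
    list(samples = list(one, one), theta_spec = ts,
         psrf = list(multivariate = 1), settings = list(), seed = 1),
    class = "posterior_ensemble"
  )
  pp <- posterior_predictive(ens, ds$data$plots, ds$theta, n_draws = 8,
                             seed = 3)
  expect_equal(pp$summary$pred_lo, pp$summary$pred_hi)
  expect_equal(dim(pp$draws), c(nrow(pp$obs), 8))
})
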