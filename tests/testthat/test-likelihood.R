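test_that("Student-t likelihood sums location-scale densities", {
  obs <- c(10, 20, 3)
  vars <- c("dbh", "dbh", "lai")
  sigma <- c(dbh = 2, lai = 0.5)
  # zero residuals: direct density evaluation at 0
  ll <- student_t_log_likelihood(obs, obs, vars, sigma, u = 4)
  expect_equal(ll, 2 * (dt(0, 4, log = TRUE) - log(2)) +
                 (dt(0, 4, log = TRUE) - log(0.5)))
  # hand-evaluated t density via the gamma-function formula
  z <- 1.3; u <- 5
  dens <- gamma((u + 1) / 2) / (sqrt(u * pi) * gamma(u / 2)) *
    (1 + z^2 / u)^(-(u + 1) / 2)
  ll1 <- student_t_log_likelihood(10 + 2 * z, 10, "dbh", sigma, u = 5)
  expect_equal(ll1, log(dens) - log(2))
  expect_error(student_t_log_likelihood(1:3, 1:2, vars, sigma, 4), "one prediction")
  expect_error(student_t_log_likelihood(obs, obs, vars, sigma, 2), "u must")
})

test_that("large degrees of freedom recover the Gaussian likelihood", {
  set.seed(5)
  o <- rnorm(50, 10, 2)
  p <- rnorm(50, 10, 2)
  sigma <- c(dbh = 1.5)
  ll_t <- student_t_log_likelihood(o, p, rep("dbh", 50), sigma, u = 1e5)
  ll_g <- sum(dnorm(o, p, 1.5, log = TRUE))
  expect_lt(abs(ll_t - ll_g) / 50, 1e-3)
})

test_that("heavy tails penalise an outlier less than the Gaussian", {
  sigma <- c(dbh = 1)
  base_t <- student_t_log_likelihood(0, 0, "dbh", sigma, u = 4)
  base_g <- dnorm(0, log = TRUE)
  out_t <- student_t_log_likelihood(10, 0, "dbh", sigma, u = 4)
  out_g <- dnorm(10, log = TRUE)
  expect_gt(base_t - out_t, 0)
  expect_lt(base_t - out_t, base_g - out_g)
})

test_that("the log-posterior is -Inf outside the prior box", {
  ds <- fixture_dataset(n_plots = 4)
  ts <- reduced_theta_spec(fixture_priors())
  lp <- make_log_posterior(ds$data$plots, ts, ds$theta,
                           error = list(sigma = ds$data$noise_scales, u = 5))
  th <- ds$theta[ts$name]
  expect_true(is.finite(lp(th)))
  th_bad <- th
  th_bad[3] <- ts$upper[3] * 1.01
  expect_identical(lp(th_bad), -Inf)
})

test_that("noise-free observations attain the zero-residual maximum at truth", {
  ds <- fixture_dataset(n_plots = 4, noise_rel = 1e-12)
  ts <- reduced_theta_spec(fixture_priors())
  sigma <- setNames(rep(1, length(observation_variables())),
                    observation_variables())
  lp <- make_log_posterior(ds$data$plots, ts, ds$theta,
                           error = list(sigma = sigma, u = 5))
  n_obs <- nrow(do.call(rbind, lapply(ds$data$plots, `[[`, "obs")))
  # with all residuals ~0 and unit scales the likelihood is n * log t(0)
  expect_equal(lp(ds$theta[ts$name]), n_obs * dt(0, 5, log = TRUE),
               tolerance = 1e-6)
})

test_that("the log-posterior composes the simulator with the t likelihood", {
  ds <- fixture_dataset(n_plots = 2)
  ts <- reduced_theta_spec(fixture_priors())
  sigma <- ds$data$noise_scales
  lp <- make_log_posterior(ds$data$plots, ts, ds$theta,
                           error = list(sigma = sigma, u = 5))
  theta <- ds$theta[ts$name] * 1.02
  params <- ds$theta
  params[ts$name] <- theta
  # hand chaining: run the simulator per plot and sum t densities
  ll <- 0
  for (pl in ds$data$plots) {
    out <- run_simulation(pl$site, pl$climate, params, pl$init_state,
                          pl$events)
    key <- out$year * 12 + out$month
    for (r in seq_len(nrow(pl$obs))) {
      row <- match(pl$obs$year[r] * 12 + pl$obs$month[r], key)
      v <- pl$obs$variable[r]
      pred <- switch(v,
        stem_biomass = out$ws[row], foliage_biomass = out$wf[row],
        root_biomass = out$wr[row], n_trees = out$n_trees[row],
        dbh = out$dbh[row], basal_area = out$basal_area[row],
        lai = out$lai[row], gpp = sum(out$gpp[(row - 11):row]) * 0.5
      )
      ll <- ll + dt((pl$obs$value[r] - pred) / sigma[[v]], 5, log = TRUE) -
        log(sigma[[v]])
    }
  }
  expect_equal(lp(theta), ll)
})
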