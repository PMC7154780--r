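#!/usr/bin/env Rscript
# Posterior-predictive evaluation and cross-validation: draws from the
# posterior, reruns the simulator per plot, and reports pBias / RMSE / NRMSE
# (plot-first averaging) on held-out plots.
#
# Requires: results/posterior_samples.csv from 02_calibrate.R
#
# Outputs (results/):
#   prediction_statistics.csv      skill on all plots
#   prediction_statistics_cv.csv   skill on the held-out half
library(pgfusion)

seed <- 20240917
n_draws <- 200 # posterior-predictive draws (1,000 in the full protocol)

theta_star <- default_parameters("picea")
net_cfg <- network_config(n_plots = 20, species = "picea")
network <- generate_monitoring_network(net_cfg, seed = seed)
dataset <- generate_observations(theta_star, network, net_cfg,
                                 climate_config(), seed = seed + 1,
                                 init_from = "truth")

prior <- make_prior_specification(read_parameter_table(
  system.file("extdata", "priors_synthetic.csv", package = "pgfusion")
))
theta_spec <- reduced_theta_spec(prior)

samples <- read.csv("results/posterior_samples.csv")
chains <- lapply(split(samples[theta_spec$name], samples$chain), as.matrix)
ensemble <- structure(
  list(samples = chains, theta_spec = theta_spec,
       psrf = list(multivariate = NA), settings = list(), seed = seed),
  class = "posterior_ensemble"
)

message("posterior predictive on all plots ...")
pp <- posterior_predictive(ensemble, dataset$plots, theta_star,
                           n_draws = n_draws, seed = seed + 3)
stats_all <- prediction_statistics(pp$obs, pp$draws)
write.csv(stats_all, "results/prediction_statistics.csv", row.names = FALSE)
print(stats_all, digits = 3)

message("50/50 cross-validation (skill on the held-out half) ...")
split_ids <- cross_validation_split(
  vapply(dataset$plots, `[[`, character(1), "plot_id"), seed = seed + 4
)
held_out <- dataset$plots[vapply(dataset$plots, function(p) {
  p$plot_id %in% split_ids$validation
}, logical(1))]
pp_cv <- posterior_predictive(ensemble, held_out, theta_star,
                              n_draws = n_draws, seed = seed + 5)
stats_cv <- prediction_statistics(pp_cv$obs, pp_cv$draws)
write.csv(stats_cv, "results/prediction_statistics_cv.csv",
          row.names = FALSE)
print(stats_cv, digits = 3)
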