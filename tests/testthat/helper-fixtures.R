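# Shared fixtures, generated in code.

fixture_site <- function(elevation = 800, asw_max = 150, fr = 0.5) {
  list(latitude = 47, elevation = elevation, asw_max = asw_max,
       asw_init = 0.75 * asw_max, fertility_rating = fr)
}

fixture_climate <- function(years = 1980:1984, elevation = 800, seed = 11,
                            ...) {
  generate_climate_series(list(elevation = elevation),
                          climate_config(...), years, seed = seed)
}

fixture_state <- function(age = 30, n = 1500, ws = 120) {
  new_stand_state(age = age, n_trees = n, ws = ws, wf = ws * 0.06,
                  wr = ws * 0.2, asw = 110)
}

fixture_priors <- function() {
  make_prior_specification(read_parameter_table(
    system.file("extdata", "priors_synthetic.csv", package = "pgfusion")
  ))
}

# A small synthetic monitoring dataset shared across calibration tests.
fixture_dataset <- function(n_plots = 6, seed = 42, noise_rel = 0.05,
                            species = "picea") {
  theta <- default_parameters(species)
  cfg <- network_config(n_plots = n_plots, species = species,
                        noise_rel = noise_rel)
  net <- generate_monitoring_network(cfg, seed = seed)
  obs <- generate_observations(theta, net, cfg, climate_config(),
                               seed = seed + 1)
  list(theta = theta, config = cfg, network = net, data = obs)
}

# Random admissible parameter vector for property tests: jitters every
# parameter within sensible multiplicative bounds around the defaults.
random_admissible_params <- function() {
  p <- default_parameters("picea")
  jitter_names <- setdiff(names(p), c("leaf_grow", "leaf_fall", "min_cond",
                                      "m0", "full_can_age"))
  p[jitter_names] <- p[jitter_names] * runif(length(jitter_names), 0.8, 1.2)
  # keep hard invariants intact
  p["y"] <- runif(1, 0.4, 0.55)
  p["t_min"] <- runif(1, -4, 0)
  p["t_opt"] <- runif(1, 12, 18)
  p["t_max"] <- runif(1, 30, 36)
  for (nm in c("m_f", "m_r", "m_s", "p_rx", "p_rn", "fn0", "k_frost",
               "max_intcptn", "sw_const")) {
    p[nm] <- min(p[nm], 0.99)
  }
  p
}
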