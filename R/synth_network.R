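# Seeded generator for monitoring networks: inventory-style plots (decadal
# revisits, management year unknown and drawn between visits), experimental
# plots (5-12 year revisits, management at measurement years), and one
# intensive/flux plot observing LAI and GPP.

#' Monitoring network configuration
#'
#' @param n_plots Number of plots (>= 2).
#' @param species `"picea"` or `"fagus"`.
#' @param elevation_range Range of plot elevations, m a.s.l.
#' @param f_nfi,f_efm Fractions of inventory-style and experimental-style
#'   plots; the remainder (at least one plot) is intensive/flux-style.
#' @param period Calendar-year range of the monitoring campaign.
#' @param revisit_nfi Revisit interval range for inventory plots, years.
#' @param revisit_efm Revisit interval range for experimental plots, years.
#' @param p_manage Probability of a thinning in an inter-visit interval.
#' @param manage_frac Range of the stem-number fraction removed by a
#'   thinning.
#' @param age_range Stand age at first visit, years.
#' @param obs_month Month of year in which measurements are taken.
#' @param noise_rel Observation noise scale as a fraction of each variable's
#'   network-wide mean.
#' @param noise_df Student-t degrees of freedom of observation noise.
#' @return Config list.
#' @export
network_config <- function(n_plots = 20, species = "picea",
                           elevation_range = c(500, 1800),
                           f_nfi = 0.55, f_efm = 0.35,
                           period = c(1980, 2017),
                           revisit_nfi = c(9, 11), revisit_efm = c(5, 12),
                           p_manage = 0.4, manage_frac = c(0.15, 0.35),
                           age_range = c(25, 70), obs_month = 7,
                           noise_rel = 0.05, noise_df = 5) {
  stopifnot(n_plots >= 2)
  as.list(environment())
}

#' Generate a monitoring network
#'
#' Plots are spread over the elevation range; inventory-style plots get
#' roughly decadal revisits with management years drawn uniformly strictly
#' between consecutive visits, experimental-style plots get 5-12-year
#' revisits with management in measurement years; every plot has at least
#' two visits. Management years are drawn once, with the seed, and then held
#' fixed so the calibration likelihood is deterministic.
#'
#' @param config From [network_config()].
#' @param seed Integer seed.
#' @return List of plots; each has `plot_id`, `network` ("NFI", "EFM",
#'   "LWF"), `site`, `age0` (age at first visit), `visit_years`,
#'   `management` (data frame `year`, `frac_removed`), and `init` (stocking
#'   and relative stocking used to seed the truth run).
#' @export
generate_monitoring_network <- function(config, seed = NULL) {
  cf <- config
  with_seed(seed, {
    n <- cf$n_plots
    n_nfi <- round(n * cf$f_nfi)
    n_efm <- round(n * cf$f_efm)
    n_lwf <- max(n - n_nfi - n_efm, 1)
    n_nfi <- n - n_efm - n_lwf
    nets <- c(rep("NFI", n_nfi), rep("EFM", n_efm), rep("LWF", n_lwf))
    elev <- seq(cf$elevation_range[1], cf$elevation_range[2], length.out = n)
    elev <- elev[sample.int(n)]
    lapply(seq_len(n), function(i) {
      first <- round(runif(1, cf$period[1], cf$period[1] +
                             (cf$period[2] - cf$period[1]) / 3))
      iv_range <- switch(nets[i],
        EFM = cf$revisit_efm,
        LWF = c(3, 5), # intensive monitoring revisits more often
        cf$revisit_nfi
      )
      visits <- first
      repeat {
        nxt <- visits[length(visits)] +
          round(runif(1, iv_range[1], iv_range[2]))
        if (nxt > cf$period[2]) break
        visits <- c(visits, nxt)
      }
      if (length(visits) < 2) visits <- c(first, cf$period[2]) # criterion: >= 2
      mgmt <- NULL
      for (j in seq_len(length(visits) - 1)) {
        if (runif(1) < cf$p_manage) {
          yr <- if (nets[i] == "EFM") {
            visits[j + 1] # at a measurement year
          } else {
            lo <- visits[j] + 1
            hi <- visits[j + 1] - 1
            if (hi < lo) next
            sample(lo:hi, 1) # strictly between consecutive visits
          }
          mgmt <- rbind(mgmt, data.frame(
            year = yr, frac_removed = runif(1, cf$manage_frac[1],
                                            cf$manage_frac[2])
          ))
        }
      }
      age0 <- round(runif(1, cf$age_range[1], cf$age_range[2]))
      asw_max <- runif(1, 100, 200)
      list(
        plot_id = sprintf("%s_%02d", nets[i], i),
        network = nets[i],
        species = cf$species,
        site = list(
          latitude = runif(1, 46.2, 47.5),
          elevation = elev[i],
          asw_max = asw_max,
          asw_init = 0.75 * asw_max,
          fertility_rating = runif(1, 0.3, 0.8)
        ),
        age0 = age0,
        visit_years = visits,
        obs_month = cf$obs_month,
        management = mgmt,
        init = list(
          n0 = max(300, 10000 * exp(-0.045 * (age0 - 2)) *
                     exp(rnorm(1, 0, 0.2))),
          rel_stocking = runif(1, 0.35, 0.85)
        )
      )
    })
  })
}

# Truth initial state for a plot at its first visit: stocking from the
# age-based thinning curve, stem pool placed at the plot's relative position
# below the self-thinning boundary, foliage/root pools at typical ratios.
plot_initial_state <- function(plot, params) {
  p <- as.list(params)
  n0 <- plot$init$n0
  ws_tree_max <- p$w_sx1000 * (1000 / n0)^p$thin_power
  ws_tree <- plot$init$rel_stocking * ws_tree_max
  ws <- ws_tree * n0 / 1000
  wf <- ws * if (p$leaf_grow > 0) 0.035 else 0.06
  wr <- ws * 0.2
  new_stand_state(age = plot$age0, n_trees = n0, ws = ws, wf = wf, wr = wr,
                  asw = plot$site$asw_init)
}

#' Generate noisy observations from a known parameter vector
#'
#' Runs the simulator at the generating parameters for every plot (applying
#' the plot's management history as absolute residual stockings, recorded as
#' the thinnings happen), samples the observable variables at visit dates,
#' and adds location-scale Student-t noise. Inventory and experimental plots
#' observe stem/foliage/root biomass, stem number, DBH and basal area;
#' intensive (LWF/flux) plots additionally observe LAI and trailing-annual
#' GPP. The noise-free truth is retained for test oracles.
#'
#' @param theta_star Full parameter vector (the synthetic truth).
#' @param network From [generate_monitoring_network()].
#' @param config The [network_config()] used (for noise settings).
#' @param climate_cfg A [climate_config()].
#' @param seed Integer seed.
#' @param init_from `"observations"` (default): calibration plots are
#'   initialised from the noisy first-visit observations, as a field
#'   campaign would be; `"truth"`: from the noise-free first-visit state,
#'   which keeps parameter-recovery experiments well posed (the inference
#'   model then matches the generating process exactly).
#' @return List: `observations` (data frame `plot_id`, `year`, `month`,
#'   `variable`, `value`, `network`), `truth` (same rows, noise-free),
#'   `plots` (calibration-ready plot list: site, climate, init_state,
#'   events, obs), `noise_scales`, `theta_star`.
#' @export
generate_observations <- function(theta_star, network, config, climate_cfg,
                                  seed = NULL,
                                  init_from = c("observations", "truth")) {
  init_from <- match.arg(init_from)
  theta_star <- validate_parameters(theta_star)
  cf <- config
  with_seed(seed, {
    plot_seeds <- sample.int(2^31 - 2, length(network))
    sim <- lapply(seq_along(network), function(i) {
      pl <- network[[i]]
      years <- (pl$visit_years[1]):(pl$visit_years[length(pl$visit_years)])
      climate <- generate_climate_series(pl$site, climate_cfg, years,
                                         seed = plot_seeds[i])
      # the first visit describes the initial state itself; simulation (and
      # the climate window) starts the month after it
      key <- climate$year * 12 + climate$month
      k0 <- pl$visit_years[1] * 12 + pl$obs_month
      k1 <- pl$visit_years[length(pl$visit_years)] * 12 + pl$obs_month
      climate <- climate[key > k0 & key <= k1, ]
      rownames(climate) <- NULL
      init <- plot_initial_state(pl, theta_star)
      # simulate segment-by-segment so each thinning's residual stocking can
      # be recorded as an absolute number, as an inventory would
      events <- NULL
      state <- init
      out <- NULL
      seg_breaks <- if (is.null(pl$management)) integer(0) else
        sort(pl$management$year)
      cursor <- 1
      months_total <- nrow(climate)
      for (b in c(seg_breaks, NA)) {
        end <- if (is.na(b)) {
          months_total
        } else {
          which(climate$year == b & climate$month == pl$obs_month)
        }
        if (length(end) == 0 || end < cursor) next
        if (end >= cursor) {
          seg <- run_simulation(pl$site, climate[cursor:end, , drop = FALSE],
                                theta_star, state)
          out <- rbind(out, seg)
          last <- seg[nrow(seg), ]
          # segment boundaries fall in the observation month (mid growing
          # season), where the deciduous foliage debt is zero, so carrying
          # the previous debt (0) across segments is exact
          state <- new_stand_state(last$age, last$n_trees, last$ws, last$wf,
                                   last$wr, last$asw,
                                   wf_debt = state$wf_debt)
          if (!is.na(b)) {
            fr_rm <- pl$management$frac_removed[pl$management$year == b][1]
            residual <- state$n_trees * (1 - fr_rm)
            ev <- list(residual_stems = residual, frac_foliage = 1,
                       frac_root = 1, frac_stem = 1)
            # the thinning takes effect after the measurement month (the
            # 1/24-year offset places it in the following month), so
            # measurements are pre-thinning
            events <- rbind(events, data.frame(
              age = state$age + 1 / 24, residual_stems = residual,
              frac_foliage = 1, frac_root = 1, frac_stem = 1
            ))
            state <- apply_management(state, ev)
          }
          cursor <- end + 1
        }
      }
      # the segmented pass above fixes the absolute residual stockings; the
      # definitive truth is the one-pass run with those events, which is
      # exactly the trajectory the calibration likelihood reproduces
      out <- run_simulation(pl$site, climate, theta_star, init, events)
      rownames(out) <- NULL
      list(plot = pl, climate = climate, init = init, out = out,
           events = events)
    })

    # truth at visit dates: the first visit reports the initial state, later
    # visits the one-pass trajectory (what the calibration reproduces)
    truth <- do.call(rbind, lapply(sim, function(s) {
      pl <- s$plot
      vars <- c("stem_biomass", "foliage_biomass", "root_biomass", "n_trees",
                "dbh", "basal_area")
      if (pl$network == "LWF") vars <- c(vars, "lai", "gpp")
      rows <- match(pl$visit_years * 12 + pl$obs_month,
                    s$out$year * 12 + s$out$month)
      attr0 <- derive_stand_attributes(s$init$n_trees, s$init$ws, s$init$wf,
                                       s$init$age, theta_star)
      do.call(rbind, lapply(seq_along(rows), function(vi) {
        r <- rows[vi]
        vv <- vars
        if (vi == 1 || r < 12) vv <- setdiff(vv, "gpp") # needs 12-mo history
        val <- vapply(vv, function(v) {
          if (vi == 1) {
            switch(v,
              stem_biomass = s$init$ws, foliage_biomass = s$init$wf,
              root_biomass = s$init$wr, n_trees = s$init$n_trees,
              dbh = attr0$dbh, basal_area = attr0$basal_area,
              lai = attr0$lai
            )
          } else if (v == "gpp") {
            sum(s$out$gpp[(r - 11):r]) * 0.5
          } else {
            s$out[[OBS_OUTPUT_COLUMN[[v]]]][r]
          }
        }, numeric(1))
        data.frame(plot_id = pl$plot_id, year = pl$visit_years[vi],
                   month = pl$obs_month, variable = vv, value = val,
                   network = pl$network, stringsAsFactors = FALSE,
                   row.names = NULL)
      }))
    }))

    scales <- vapply(split(truth$value, truth$variable), mean, numeric(1))
    scales <- cf$noise_rel * scales[OBS_VARIABLES]
    names(scales) <- OBS_VARIABLES
    obs <- truth
    obs$value <- pmax(
      truth$value + scales[truth$variable] * rt(nrow(truth), df = cf$noise_df),
      0
    )

    # calibration-ready plots: initial state from the first-visit
    # *observations* (the first record initialises the model), later visits
    # enter the likelihood
    plots <- lapply(sim, function(s) {
      pl <- s$plot
      o <- obs[obs$plot_id == pl$plot_id, ]
      first_year <- pl$visit_years[1]
      f <- if (init_from == "observations") {
        o[o$year == first_year, ]
      } else {
        tr <- truth[truth$plot_id == pl$plot_id, ]
        tr[tr$year == first_year, ]
      }
      val <- function(v) f$value[f$variable == v][1]
      init_state <- new_stand_state(
        age = pl$age0, n_trees = val("n_trees"), ws = val("stem_biomass"),
        wf = val("foliage_biomass"), wr = val("root_biomass"),
        asw = pl$site$asw_init
      )
      list(
        plot_id = pl$plot_id, network = pl$network, site = pl$site,
        climate = s$climate, init_state = init_state, events = s$events,
        obs = o[o$year != first_year,
                c("year", "month", "variable", "value")]
      )
    })
    list(observations = obs, truth = truth, plots = plots,
         noise_scales = scales, theta_star = theta_star)
  })
}
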