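# Regional NPP analysis: spin-up, paired reference/scenario runs over a
# habitat grid, anomaly maps, elevation-gradient slopes and climate-year
# classification.

#' Spin up a stand to age 40 under climatological forcing
#'
#' Stands start as 2-year-old plantations at 10,000 trees/ha and are thinned
#' at ages 20 and 35 so stocking lands near 1,000 trees/ha at age 40; the
#' forcing is a repeated month-wise climatological year.
#'
#' @param site Site list.
#' @param clim_year 12-row climatological year ([climatological_year()]).
#' @param params Parameter vector.
#' @param init_density Planting density, trees/ha (default 10000).
#' @param thin_ages,thin_residuals Thinning ages (years) and residual
#'   stockings (trees/ha); defaults age 20 -> 2400 and age 35 -> 1050.
#' @return Stand state at age 40, or NULL if the stand collapsed (all pools
#'   zero) during spin-up.
#' @export
spin_up_stand <- function(site, clim_year, params, init_density = 10000,
                          thin_ages = c(20, 35),
                          thin_residuals = c(2400, 1050)) {
  pools <- pools_from_structure(init_density, dbh = 1, params,
                                wf_ratio = 0.3, wr_ratio = 0.4)
  state <- new_stand_state(age = 2, n_trees = init_density, ws = pools$ws,
                           wf = pools$wf, wr = pools$wr,
                           asw = site$asw_max)
  years <- seq_len(38) # age 2 -> 40
  climate <- repeat_climatology(clim_year, years)
  events <- management_schedule(thin_ages, thin_residuals)
  out <- run_simulation(site, climate, params, state, events)
  last <- out[nrow(out), ]
  if (last$ws <= 0 || last$n_trees <= 0) return(NULL)
  new_stand_state(last$age, last$n_trees, last$ws, last$wf, last$wr,
                  last$asw)
}

#' Run one scenario period from a spun-up state
#'
#' Simulates the supplied monthly climate (28-30 years) from the common
#' age-40 state and returns the annual NPP series in Mg C/ha/yr (calendar
#' years; stand ages 41-70, the early-development ages having been excluded
#' by construction).
#'
#' @param site Site list.
#' @param period_climate Monthly climate data frame.
#' @param spin_state Age-40 stand state from [spin_up_stand()].
#' @param params Parameter vector.
#' @return List `annual` (data frame `year`, `npp_c`) and `mean_npp_c`.
#' @export
run_scenario_period <- function(site, period_climate, spin_state, params) {
  n_years <- nrow(period_climate) / 12
  if (n_years < 28) stop("scenario climate must cover at least 28 years")
  out <- run_simulation(site, period_climate, params, spin_state)
  ann <- annual_aggregate(out)
  ann <- ann[ann$n_months == 12, ]
  list(annual = data.frame(year = ann$year, npp_c = ann$npp_c),
       mean_npp_c = mean(ann$npp_c))
}

#' Full paired reference/scenario analysis over a habitat grid
#'
#' For every habitat cell: generate paired reference and scenario climate
#' (shared per-cell seed), build the reference climatology, spin up to age
#' 40, run both periods from the common state, and collect annual NPP.
#' Collapsed cells are flagged and excluded.
#'
#' @param grid From [generate_country_grid()].
#' @param climate_cfg A [climate_config()]; its `extreme_years` apply to the
#'   scenario period.
#' @param params Parameter vector.
#' @param ref_years,scn_years Calendar years of the reference and scenario
#'   periods (defaults 1961-1990 and 1991-2018).
#' @return Object of class `regional_result`: `cells` (per-cell elevation,
#'   reference and scenario mean NPP), `annual_scn` (matrix cells x scenario
#'   years of annual NPP), `scn_years`, and `excluded` cell ids.
#' @export
run_regional_analysis <- function(grid, climate_cfg, params,
                                  ref_years = 1961:1990,
                                  scn_years = 1991:2018) {
  cells <- grid[grid$habitat, ]
  params <- validate_parameters(params)
  ref_cfg <- climate_cfg
  ref_cfg$extreme_years <- NULL # extremes are scenario features
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    site <- grid_cell_site(grid, cell$cell_id)
    ref_climate <- generate_climate_series(site, ref_cfg, ref_years,
                                           seed = cell$climate_seed)
    scn_climate <- generate_climate_series(site, climate_cfg, scn_years,
                                           seed = cell$climate_seed + 1)
    clim_year <- climatological_year(ref_climate)
    spin <- spin_up_stand(site, clim_year, params)
    if (is.null(spin)) {
      res[[i]] <- NULL
      next
    }
    ref <- run_scenario_period(site, ref_climate, spin, params)
    scn <- run_scenario_period(site, scn_climate, spin, params)
    res[[i]] <- list(
      cell_id = cell$cell_id, elevation = cell$elevation,
      npp_ref = ref$mean_npp_c, npp_scn = scn$mean_npp_c,
      annual_scn = scn$annual$npp_c
    )
  }
  ok <- !vapply(res, is.null, logical(1))
  excluded <- cells$cell_id[!ok]
  res <- res[ok]
  annual <- do.call(rbind, lapply(res, function(r) r$annual_scn))
  structure(
    list(
      cells = data.frame(
        cell_id = vapply(res, `[[`, numeric(1), "cell_id"),
        elevation = vapply(res, `[[`, numeric(1), "elevation"),
        npp_ref = vapply(res, `[[`, numeric(1), "npp_ref"),
        npp_scn = vapply(res, `[[`, numeric(1), "npp_scn")
      ),
      annual_scn = annual, scn_years = scn_years,
      excluded = excluded
    ),
    class = "regional_result"
  )
}

#' Per-cell NPP anomalies and affected-area fractions
#'
#' The anomaly of a year is the percentage deviation of that year's NPP from
#' the cell's reference-period mean. The affected-area fraction counts cells
#' strictly below the threshold.
#'
#' @param results A `regional_result`.
#' @param years Scenario years to map.
#' @param threshold Anomaly threshold in percent (default -25).
#' @return List `anomalies` (data frame `cell_id`, `elevation`, one column
#'   per selected year) and `affected_fraction` (named vector, percent of
#'   habitat cells with anomaly strictly below the threshold).
#' @export
anomaly_map <- function(results, years, threshold = -25) {
  stopifnot(inherits(results, "regional_result"))
  if (any(results$cells$npp_ref <= 0)) {
    stop("anomalies undefined where reference NPP is zero")
  }
  cols <- match(years, results$scn_years)
  if (anyNA(cols)) stop("year outside the scenario period")
  anom <- sapply(cols, function(j) {
    100 * (results$annual_scn[, j] - results$cells$npp_ref) /
      results$cells$npp_ref
  })
  anom <- matrix(anom, nrow = nrow(results$cells))
  colnames(anom) <- as.character(years)
  frac <- 100 * colSums(anom < threshold) / nrow(anom)
  names(frac) <- as.character(years)
  list(
    anomalies = cbind(results$cells[c("cell_id", "elevation")],
                      as.data.frame(anom)),
    affected_fraction = frac
  )
}

#' Elevation gradient of mean NPP
#'
#' Ordinary least squares of period-mean NPP per cell on elevation in km.
#'
#' @param results A `regional_result`.
#' @param period `"scenario"` (default) or `"reference"`.
#' @return List `slope` (Mg C ha-1 yr-1 km-1), `se`, `p_value`, `fit`.
#' @export
elevation_gradient_slope <- function(results, period = c("scenario",
                                                         "reference")) {
  period <- match.arg(period)
  cells <- results$cells
  if (nrow(cells) < 3) stop("need at least 3 cells")
  if (length(unique(cells$elevation)) < 2) {
    stop("elevation is constant; slope undefined")
  }
  npp <- if (period == "scenario") cells$npp_scn else cells$npp_ref
  elev_km <- cells$elevation / 1000
  fit <- lm(npp ~ elev_km)
  sm <- summary(fit)$coefficients
  list(slope = sm["elev_km", "Estimate"], se = sm["elev_km", "Std. Error"],
       p_value = sm["elev_km", "Pr(>|t|)"], fit = fit)
}

#' Growing-season climate statistics of a multi-year series
#'
#' Mean April-October temperature and precipitation sum per year, with their
#' across-year means and SDs (the reference climatology used for
#' classification).
#'
#' @param climate Monthly climate data frame.
#' @param months Growing-season months (default 4:10).
#' @return List `per_year` (data frame `year`, `t_gs`, `p_gs`), `t_mean`,
#'   `t_sd`, `p_mean`, `p_sd`.
#' @export
growing_season_stats <- function(climate, months = 4:10) {
  gs <- climate[climate$month %in% months, ]
  t_gs <- tapply((gs$tmin + gs$tmax) / 2, gs$year, mean)
  p_gs <- tapply(gs$prcp, gs$year, sum)
  per_year <- data.frame(year = as.integer(names(t_gs)),
                         t_gs = as.numeric(t_gs), p_gs = as.numeric(p_gs))
  list(per_year = per_year, t_mean = mean(per_year$t_gs),
       t_sd = sd(per_year$t_gs), p_mean = mean(per_year$p_gs),
       p_sd = sd(per_year$p_gs))
}

#' Classify a year against a reference climatology
#'
#' Standardised growing-season temperature and precipitation anomalies;
#' a quadrant label (warm/cold x dry/wet) is assigned when either |z|
#' exceeds the extremeness threshold, otherwise `normal`.
#'
#' @param year_climate 12-row climate data frame for the year.
#' @param ref_stats Output of [growing_season_stats()] on at least 10
#'   reference years.
#' @param threshold Extremeness threshold in SD units (default 1.5).
#' @param months Growing-season months (default 4:10).
#' @return List `label`, `z_t`, `z_p`.
#' @export
classify_climate_year <- function(year_climate, ref_stats, threshold = 1.5,
                                  months = 4:10) {
  if (nrow(ref_stats$per_year) < 10) {
    stop("reference climatology needs >= 10 years")
  }
  gs <- year_climate[year_climate$month %in% months, ]
  z_t <- (mean((gs$tmin + gs$tmax) / 2) - ref_stats$t_mean) / ref_stats$t_sd
  z_p <- (sum(gs$prcp) - ref_stats$p_mean) / ref_stats$p_sd
  label <- if (max(abs(z_t), abs(z_p)) < threshold) {
    "normal"
  } else {
    paste0(if (z_t > 0) "warm" else "cold",
           "_",
           if (z_p <= 0) "dry" else "wet")
  }
  list(label = label, z_t = z_t, z_p = z_p)
}
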