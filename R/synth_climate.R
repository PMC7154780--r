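# Seeded generator for elevation-structured monthly climate with injectable
# extreme years. Intentionally stylised (sinusoidal seasonal cycles, a linear
# lapse rate, interannual noise): enough structure to induce the
# elevation-dependent limitation regimes the analysis probes, without
# reproducing any real meteorology.

#' Climate generator configuration
#'
#' Defaults describe a temperate-montane setting: ~9.5 degC annual mean at
#' sea level with a 9 degC seasonal amplitude and a 5.5 degC/km lapse rate;
#' precipitation around 85 mm/month at sea level, wetter in summer and at
#' elevation; frost days from a logistic function of the monthly minimum
#' temperature.
#'
#' @param t_mean_sl Annual mean temperature at sea level, degC.
#' @param t_amp Seasonal temperature amplitude, degC (peak July).
#' @param dtr Diurnal temperature range (tmax - tmin), degC.
#' @param lapse_rate Temperature lapse rate, degC per km elevation.
#' @param t_year_sd,t_month_sd Interannual / within-year monthly temperature
#'   noise SDs, degC.
#' @param prcp_mean Mean monthly precipitation at sea level, mm.
#' @param prcp_amp Seasonal precipitation amplitude, mm (peak July).
#' @param prcp_elev_grad Precipitation increase per km elevation, mm/month.
#' @param prcp_cv Lognormal coefficient of variation of monthly
#'   precipitation.
#' @param srad_mean,srad_amp,srad_sd Shortwave radiation cycle
#'   (MJ m-2 day-1) and noise SD.
#' @param frost_t0,frost_scale Logistic frost-day model: frost days =
#'   days * plogis((frost_t0 - tmin)/frost_scale).
#' @param co2 Constant atmospheric CO2, ppm.
#' @param extreme_years Data frame `year`, `type` (warm_dry, cold_dry,
#'   warm_wet, cold_wet), `z_t`, `z_p` (anomaly magnitudes, in units of the
#'   generator's temperature SD and relative precipitation CV).
#' @return Config list.
#' @export
climate_config <- function(t_mean_sl = 9.5, t_amp = 9, dtr = 9,
                           lapse_rate = 5.5, t_year_sd = 0.5,
                           t_month_sd = 0.9, prcp_mean = 85, prcp_amp = 30,
                           prcp_elev_grad = 35, prcp_cv = 0.25,
                           srad_mean = 11, srad_amp = 8.5, srad_sd = 0.8,
                           frost_t0 = 0.5, frost_scale = 2.2, co2 = 380,
                           extreme_years = NULL) {
  as.list(environment())
}

#' Generate a monthly climate series for a site
#'
#' Sinusoidal seasonal cycles plus seeded interannual noise; temperature
#' decreases linearly with elevation; frost days follow a logistic function
#' of the monthly minimum temperature; configured extreme years get an
#' additive temperature anomaly and a multiplicative precipitation anomaly.
#' Deterministic per (site, config, years, seed).
#'
#' @param site List with `elevation` (m a.s.l.).
#' @param config From [climate_config()].
#' @param years Integer vector of calendar years.
#' @param seed Integer seed.
#' @return Data frame with columns `year`, `month`, `tmin`, `tmax`, `prcp`,
#'   `srad`, `frost_days`, `co2` satisfying the climate invariants.
#' @export
generate_climate_series <- function(site, config, years, seed = NULL) {
  cf <- config
  ny <- length(years)
  elev_km <- site$elevation / 1000
  with_seed(seed, {
    year_anom <- rnorm(ny, 0, cf$t_year_sd)
    grid <- expand.grid(month = 1:12, year = years)
    m <- grid$month
    y_i <- rep(seq_len(ny), each = 12)
    season <- cos(2 * pi * (m - 7) / 12)
    tmean <- cf$t_mean_sl - cf$lapse_rate * elev_km + cf$t_amp * season +
      year_anom[y_i] + rnorm(12 * ny, 0, cf$t_month_sd)
    prcp_base <- pmax(cf$prcp_mean + cf$prcp_elev_grad * elev_km +
                        cf$prcp_amp * season, 0)
    prcp <- prcp_base *
      exp(rnorm(12 * ny, 0, cf$prcp_cv) - cf$prcp_cv^2 / 2)
    srad <- pmax(cf$srad_mean + cf$srad_amp * season +
                   rnorm(12 * ny, 0, cf$srad_sd), 0.5)
    if (!is.null(cf$extreme_years) && nrow(cf$extreme_years)) {
      for (r in seq_len(nrow(cf$extreme_years))) {
        ex <- cf$extreme_years[r, ]
        sel <- grid$year == ex$year
        if (!any(sel)) next
        tmean[sel] <- tmean[sel] + ex$z_t * cf$t_month_sd
        prcp[sel] <- prcp[sel] * pmax(1 + ex$z_p * cf$prcp_cv, 0.05)
      }
    }
    tmin <- tmean - cf$dtr / 2
    tmax <- tmean + cf$dtr / 2
    ndays <- days_in_month(grid$year, m)
    frost <- round(ndays * stats::plogis((cf$frost_t0 - tmin) /
                                           cf$frost_scale))
    data.frame(
      year = grid$year, month = m, tmin = tmin, tmax = tmax,
      prcp = prcp, srad = srad, frost_days = frost, co2 = cf$co2
    )
  })
}

#' Month-wise climatological average of a climate series
#'
#' Used as spin-up forcing: the month-wise mean over all years of every
#' climate column (frost days rounded to whole days).
#'
#' @param climate Data frame from [generate_climate_series()].
#' @param year Calendar year label to give the 12 averaged months.
#' @return 12-row climate data frame.
#' @export
climatological_year <- function(climate, year = 0) {
  agg <- aggregate(climate[c("tmin", "tmax", "prcp", "srad", "frost_days",
                             "co2")],
                   by = list(month = climate$month), FUN = mean)
  agg <- agg[order(agg$month), ]
  data.frame(
    year = year, month = agg$month, tmin = agg$tmin, tmax = agg$tmax,
    prcp = agg$prcp, srad = agg$srad,
    frost_days = round(agg$frost_days), co2 = agg$co2
  )
}

#' Repeat a climatological year over many simulation years
#'
#' @param clim_year 12-row climate data frame from [climatological_year()].
#' @param years Calendar years to label the repetitions with.
#' @return Monthly climate data frame of `12 * length(years)` rows.
#' @export
repeat_climatology <- function(clim_year, years) {
  out <- clim_year[rep(seq_len(12), length(years)), ]
  out$year <- rep(years, each = 12)
  rownames(out) <- NULL
  out
}
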