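# Plain-text interfaces: climate and observation CSVs, site YAML configs,
# tidy monthly output tables.

#' Read a monthly climate CSV
#'
#' Expected columns: `year, month, tmin_c, tmax_c, prcp_mm,
#' srad_mj_m2_day, frost_days` and optionally `co2_ppm`.
#'
#' @param path CSV path.
#' @param co2_default CO2 used when the column is absent, ppm.
#' @return Climate data frame in the package's internal column names.
#' @export
read_climate_csv <- function(path, co2_default = 380) {
  x <- read.csv(path)
  need <- c("year", "month", "tmin_c", "tmax_c", "prcp_mm",
            "srad_mj_m2_day", "frost_days")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  data.frame(
    year = x$year, month = x$month, tmin = x$tmin_c, tmax = x$tmax_c,
    prcp = x$prcp_mm, srad = x$srad_mj_m2_day, frost_days = x$frost_days,
    co2 = if ("co2_ppm" %in% names(x)) x$co2_ppm else co2_default
  )
}

#' Write a monthly climate CSV
#' @param climate Internal climate data frame.
#' @param path Output path.
#' @export
write_climate_csv <- function(climate, path) {
  write.csv(
    data.frame(
      year = climate$year, month = climate$month, tmin_c = climate$tmin,
      tmax_c = climate$tmax, prcp_mm = climate$prcp,
      srad_mj_m2_day = climate$srad, frost_days = climate$frost_days,
      co2_ppm = climate$co2
    ),
    path, row.names = FALSE
  )
}

#' Read a site description from YAML
#'
#' Fields: `latitude`, `elevation`, `asw_max`, `asw_init`,
#' `fertility_rating`, optional `soil_class`.
#'
#' @param path YAML path.
#' @return Site list.
#' @export
read_site_yaml <- function(path) {
  site <- yaml::read_yaml(path)
  need <- c("latitude", "elevation", "asw_max", "asw_init",
            "fertility_rating")
  missing <- setdiff(need, names(site))
  if (length(missing)) stop("missing site fields: ",
                            paste(missing, collapse = ", "))
  if (site$asw_init < 0 || site$asw_init > site$asw_max) {
    stop("asw_init must lie in [0, asw_max]")
  }
  if (site$fertility_rating < 0 || site$fertility_rating > 1) {
    stop("fertility_rating must lie in [0,1]")
  }
  site
}

#' Read an observation table CSV
#'
#' Columns: `plot_id, date, variable, value, network_tag` with `date` in ISO
#' year-month (`YYYY-MM`) form.
#'
#' @param path CSV path.
#' @return Data frame `plot_id`, `year`, `month`, `variable`, `value`,
#'   `network`.
#' @export
read_observation_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "date", "variable", "value", "network_tag")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(x$variable), OBS_VARIABLES)
  if (length(bad)) stop("unknown variables: ", paste(bad, collapse = ", "))
  if (any(x$value < 0)) stop("observation values must be >= 0")
  parts <- strsplit(x$date, "-")
  data.frame(
    plot_id = x$plot_id,
    year = as.integer(vapply(parts, `[`, character(1), 1)),
    month = as.integer(vapply(parts, `[`, character(1), 2)),
    variable = x$variable, value = x$value, network = x$network_tag,
    stringsAsFactors = FALSE
  )
}

#' Write an observation table CSV
#' @param obs Data frame as produced by [generate_observations()].
#' @param path Output path.
#' @export
write_observation_csv <- function(obs, path) {
  write.csv(
    data.frame(
      plot_id = obs$plot_id,
      date = sprintf("%04d-%02d", obs$year, obs$month),
      variable = obs$variable, value = obs$value,
      network_tag = obs$network
    ),
    path, row.names = FALSE
  )
}
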