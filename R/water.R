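# Canopy conductance, Penman-Monteith evapotranspiration and the monthly
# soil water balance.

PM_E20 <- 2.2            # slope-ratio term of the PM equation at 20 degC
PM_RHO_AIR <- 1.2        # kg/m3
PM_LAMBDA <- 2460000     # J/kg latent heat of vaporisation
PM_VPD_CONV <- 0.000622  # mbar -> specific humidity deficit (kg/kg per mbar)
PM_QA <- -90             # net radiation intercept, W/m2
PM_QB <- 0.8             # net radiation slope on incident shortwave

#' Daylight length
#'
#' Standard solar geometry for the mid-month day of year.
#'
#' @param latitude Degrees north.
#' @param month Month 1-12.
#' @return Daylight seconds.
#' @export
day_length <- function(latitude, month) {
  doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[month]
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  cosh0 <- -tan(latitude * pi / 180) * tan(decl)
  cosh0 <- pmin(pmax(cosh0, -1), 1)
  2 * acos(cosh0) / (2 * pi) * 86400
}

#' Canopy conductance
#'
#' Maximum conductance reduced by the more limiting of the VPD and soil-water
#' modifiers, the age and CO2 modifiers, and canopy closure
#' (`min(lai/lai_gcx, 1)`), floored at `min_cond`.
#'
#' @param lai Leaf area index.
#' @param modifiers Modifier list (uses `f_vpd`, `f_sw`, `f_age`, `f_cg`).
#' @param params Parameter vector.
#' @return Conductance in m/s, within `[min_cond, max_cond]`.
#' @export
canopy_conductance <- function(lai, modifiers, params) {
  p <- as.list(params)
  gc <- p$max_cond * min(modifiers$f_vpd, modifiers$f_sw) * modifiers$f_age *
    modifiers$f_cg * min(lai / p$lai_gcx, 1)
  max(gc, p$min_cond)
}

#' Penman-Monteith evaporation rate
#'
#' Monthly 3-PG form: net radiation is a linear function of incident
#' shortwave over the daylight period; the aerodynamic term uses the
#' boundary-layer conductance. Negative rates (energy-limited winter months)
#' are floored at zero.
#'
#' @param srad Monthly mean daily shortwave radiation, MJ m-2 day-1.
#' @param vpd Vapour pressure deficit, kPa.
#' @param h Daylight seconds.
#' @param gc Surface (canopy or soil) conductance, m/s.
#' @param bl_cond Boundary-layer conductance, m/s.
#' @return Evaporation in mm/day.
#' @export
penman_monteith <- function(srad, vpd, h, gc, bl_cond) {
  if (gc <= 0) return(0)
  net_rad <- PM_QA + PM_QB * (srad * 1e6 / h)
  def_term <- PM_RHO_AIR * PM_LAMBDA * PM_VPD_CONV * (vpd * 10) * bl_cond
  div <- gc * (1 + PM_E20) + bl_cond
  e <- gc * (PM_E20 * net_rad + def_term) / div # W/m2
  max(e / PM_LAMBDA * h, 0)                     # mm/day
}

#' Monthly evapotranspiration components
#'
#' Canopy transpiration (Penman-Monteith with canopy conductance), rainfall
#' interception (capped linear function of LAI), and soil evaporation
#' (Penman-Monteith with a soil surface conductance attenuated by canopy
#' shading `exp(-k * lai)`). Transpiration and soil evaporation are capped by
#' the water actually available (`asw` plus net rainfall).
#'
#' @param climate One-month climate record (`prcp`, `srad`, `tmin`, `tmax`).
#' @param lai Leaf area index.
#' @param gc Canopy conductance, m/s (> 0, or 0 for a leafless canopy).
#' @param asw Current available soil water, mm.
#' @param latitude Site latitude, degrees.
#' @param month Month 1-12.
#' @param ndays Days in month.
#' @param params Parameter vector.
#' @return Named list `transpiration`, `soil_evap`, `interception` (mm/month).
#' @export
evapotranspiration <- function(climate, lai, gc, asw, latitude, month, ndays,
                               params) {
  p <- as.list(params)
  if (gc < 0) stop("gc must be >= 0")
  vpd <- compute_vpd(climate$tmin, climate$tmax)
  h <- day_length(latitude, month)
  interception <- p$max_intcptn * min(lai / p$lai_max_intcptn, 1) *
    climate$prcp
  transp <- if (gc > 0) {
    penman_monteith(climate$srad, vpd, h, gc, p$bl_cond) * ndays
  } else {
    0
  }
  avail <- max(asw + climate$prcp - interception, 0)
  transp <- min(transp, avail)
  g_soil <- p$soil_cond * exp(-p$k * lai)
  soil_evap <- penman_monteith(climate$srad, vpd, h, g_soil, p$bl_cond) * ndays
  soil_evap <- min(soil_evap, max(avail - transp, 0))
  list(transpiration = transp, soil_evap = soil_evap,
       interception = interception)
}

#' Update the soil water store
#'
#' `asw' = clamp(asw + prcp - interception - transpiration - soil_evap, 0,
#' asw_max)`; the positive excess above `asw_max` drains off as runoff and any
#' forced clip below zero is reported so the monthly balance closes exactly:
#' `prcp = d_asw + interception + transpiration + soil_evap + runoff - clip`.
#'
#' @param asw Current store, mm.
#' @param prcp Rainfall, mm.
#' @param interception,transpiration,soil_evap Losses, mm (>= 0).
#' @param asw_max Store capacity, mm.
#' @return Named list `asw`, `runoff`, `clip`.
#' @export
update_soil_water <- function(asw, prcp, interception, transpiration,
                              soil_evap, asw_max) {
  if (any(c(prcp, interception, transpiration, soil_evap) < 0)) {
    stop("all water fluxes must be >= 0")
  }
  raw <- asw + prcp - interception - transpiration - soil_evap
  clip <- max(-raw, 0)
  runoff <- max(raw - asw_max, 0)
  list(asw = min(max(raw, 0), asw_max), runoff = runoff, clip = clip)
}
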