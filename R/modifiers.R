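# Environmental growth modifiers: dimensionless [0,1] multipliers on canopy
# quantum efficiency and conductance. Forms are the canonical monthly 3-PG
# ones (Sands & Landsberg dialect).

#' Daytime vapour pressure deficit from monthly temperature extremes
#'
#' The standard 3-PG proxy: half the difference between saturation vapour
#' pressure (Tetens form) at the monthly mean daily maximum and minimum
#' temperature.
#'
#' @param tmin,tmax Monthly means of daily minimum/maximum temperature, degC.
#' @return VPD in kPa (>= 0).
#' @export
compute_vpd <- function(tmin, tmax) {
  if (any(tmin > tmax)) stop("tmin must not exceed tmax")
  es <- function(t) 0.61078 * exp(17.269 * t / (237.3 + t))
  0.5 * (es(tmax) - es(tmin))
}

#' Temperature growth modifier
#'
#' Asymmetric hump between the cardinal temperatures: 0 at and outside
#' `t_min`/`t_max`, 1 at `t_opt`.
#'
#' @param t_av Mean monthly temperature, degC.
#' @param t_min,t_opt,t_max Cardinal temperatures, `t_min < t_opt < t_max`.
#' @return Modifier in \[0,1\].
#' @export
temperature_modifier <- function(t_av, t_min, t_opt, t_max) {
  if (!(all(t_min < t_opt) && all(t_opt < t_max))) {
    stop("cardinal temperatures must satisfy t_min < t_opt < t_max")
  }
  f <- ((t_av - t_min) / (t_opt - t_min)) *
    ((t_max - t_av) / (t_max - t_opt))^((t_max - t_opt) / (t_opt - t_min))
  f[t_av <= t_min | t_av >= t_max] <- 0
  pmin(pmax(f, 0), 1)
}

#' Frost growth modifier
#'
#' Linear penalty of `k_frost` production-days per frost day, clamped to
#' \[0,1\].
#'
#' @param frost_days Frost days in the month.
#' @param days_in_month Calendar days in the month.
#' @param k_frost Fraction of a day's production lost per frost day.
#' @return Modifier in \[0,1\].
#' @export
frost_modifier <- function(frost_days, days_in_month, k_frost) {
  if (any(frost_days < 0) || any(frost_days > days_in_month)) {
    stop("frost_days must lie in [0, days_in_month]")
  }
  pmin(pmax(1 - k_frost * (frost_days / days_in_month), 0), 1)
}

#' Vapour-pressure-deficit modifier
#'
#' Exponential stomatal closure, `exp(-coeff_cond * vpd)` with VPD expressed
#' in mbar (`coeff_cond` is tabled per mbar; 1 kPa = 10 mbar).
#'
#' @param vpd VPD in kPa (>= 0).
#' @param coeff_cond Sensitivity, mbar^-1.
#' @return Modifier in (0,1\].
#' @export
vpd_modifier <- function(vpd, coeff_cond) {
  if (any(vpd < 0)) stop("vpd must be >= 0")
  exp(-coeff_cond * vpd * 10)
}

#' Soil-water modifier
#'
#' Sigmoidal response to relative available soil water,
#' `1 / (1 + ((1 - r)/sw_const)^sw_power)` with `r = asw/asw_max`.
#'
#' @param asw Available soil water, mm.
#' @param asw_max Maximum available soil water, mm (> 0).
#' @param sw_const Relative water deficit at which the modifier is 0.5.
#' @param sw_power Shape exponent.
#' @return Modifier in (0,1\], nondecreasing in `asw`.
#' @export
soil_water_modifier <- function(asw, asw_max, sw_const, sw_power) {
  if (any(asw_max <= 0)) stop("asw_max must be > 0")
  r <- pmin(pmax(asw / asw_max, 0), 1)
  1 / (1 + ((1 - r) / sw_const)^sw_power)
}

#' Fertility modifier
#'
#' `1 - (1 - fn0) * (1 - fr)^fnn`: equals `fn0` on the poorest soils
#' (`fr = 0`) and 1 on the richest (`fr = 1`).
#'
#' @param fr Fertility rating in \[0,1\].
#' @param fn0 Modifier value at `fr = 0`.
#' @param fnn Shape exponent.
#' @return Modifier in \[0,1\].
#' @export
fertility_modifier <- function(fr, fn0, fnn) {
  if (any(fr < 0) || any(fr > 1)) stop("fr must lie in [0,1]")
  1 - (1 - fn0) * (1 - fr)^fnn
}

#' Age modifier
#'
#' Declining sigmoid of relative age, `1 / (1 + ((age/max_age)/r_age)^n_age)`;
#' 1 at age 0 and 0.5 when `age/max_age = r_age`.
#'
#' @param age Stand age, years.
#' @param max_age Maximum attainable age, years.
#' @param n_age,r_age Shape parameters.
#' @return Modifier in (0,1\].
#' @export
age_modifier <- function(age, max_age, n_age, r_age) {
  1 / (1 + ((age / max_age) / r_age)^n_age)
}

#' Atmospheric CO2 modifiers on assimilation and conductance
#'
#' Standard 3-PG hyperbolae anchored at 1 for 350 ppm and at the supplied
#' doubled-CO2 (700 ppm) responses: assimilation increases, conductance
#' decreases with CO2.
#'
#' @param co2 Atmospheric CO2, ppm.
#' @param f_calpha700 Assimilation response at 700 ppm (>= 1 typically).
#' @param f_cg700 Conductance response at 700 ppm (<= 1 typically).
#' @return Named numeric vector `c(f_calpha, f_cg)`.
#' @export
co2_modifiers <- function(co2, f_calpha700, f_cg700) {
  if (any(co2 <= 0)) stop("co2 must be > 0")
  f_calpha_x <- f_calpha700 / (2 - f_calpha700)
  f_cg0 <- f_cg700 / (2 * f_cg700 - 1)
  f_calpha <- f_calpha_x * co2 / (350 * (f_calpha_x - 1) + co2)
  f_cg <- f_cg0 / (1 + (f_cg0 - 1) * co2 / 350)
  c(f_calpha = f_calpha, f_cg = f_cg)
}

#' Assemble the full modifier set for one month
#'
#' Combines the individual modifiers and the 3-PG physiological product
#' `phys_mod = f_age * min(f_vpd, f_sw)`.
#'
#' @param climate One-row climate record (list or data.frame row) with
#'   `tmin`, `tmax`, `frost_days`, `co2`.
#' @param asw Current available soil water, mm.
#' @param age Stand age, years.
#' @param site Site list with `asw_max`, `fertility_rating`.
#' @param params Parameter vector, see [default_parameters()].
#' @param days_in_month Calendar days in the month.
#' @return Named list with all modifiers plus `vpd` (kPa) and `phys_mod`.
#' @export
compute_modifiers <- function(climate, asw, age, site, params, days_in_month) {
  p <- as.list(params)
  t_av <- (climate$tmin + climate$tmax) / 2
  vpd <- compute_vpd(climate$tmin, climate$tmax)
  co2 <- if (is.null(climate$co2) || is.na(climate$co2)) 380 else climate$co2
  fc <- co2_modifiers(co2, p$f_calpha700, p$f_cg700)
  f_vpd <- vpd_modifier(vpd, p$coeff_cond)
  f_sw <- soil_water_modifier(asw, site$asw_max, p$sw_const, p$sw_power)
  f_age <- age_modifier(age, p$max_age, p$n_age, p$r_age)
  list(
    f_t = temperature_modifier(t_av, p$t_min, p$t_opt, p$t_max),
    f_frost = frost_modifier(climate$frost_days, days_in_month, p$k_frost),
    f_vpd = f_vpd,
    f_sw = f_sw,
    f_nutr = fertility_modifier(site$fertility_rating, p$fn0, p$fnn),
    f_age = f_age,
    f_calpha = fc[["f_calpha"]],
    f_cg = fc[["f_cg"]],
    vpd = vpd,
    phys_mod = f_age * pmin(f_vpd, f_sw)
  )
}

#' Calendar days in a month
#'
#' Calendar-true, including leap Februaries (Gregorian rule).
#'
#' @param year,month Integer year and month (1-12).
#' @return Number of days.
#' @export
days_in_month <- function(year, month) {
  base <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2 & leap] <- 29
  d
}
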