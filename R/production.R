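# Light absorption, GPP/NPP, and NPP partitioning.

MOL_PHOTON_PER_MJ_PAR <- 4.6   # mol photons per MJ of PAR
G_C_PER_MOL <- 12              # g carbon per mol C
CARBON_FRACTION <- 0.5         # g C per g dry matter

#' Specific leaf area at a given stand age
#'
#' Declines from the juvenile value `sla0` to the mature value `sla1` with a
#' Gaussian-in-age ramp whose half-way point is `t_sla` years.
#'
#' @param age Stand age, years.
#' @param sla0,sla1 Juvenile/mature specific leaf area, m2/kg.
#' @param t_sla Age at which SLA is half-way between `sla0` and `sla1`, years.
#' @return SLA in m2/kg.
#' @export
specific_leaf_area <- function(age, sla0, sla1, t_sla) {
  sla1 + (sla0 - sla1) * exp(-log(2) * (age / t_sla)^2)
}

#' Monthly litterfall rate at a given stand age
#'
#' Ramps from the juvenile rate `gamma_f0` to the mature rate `gamma_f1`
#' (month^-1); `t_gamma_f` (years) controls how fast the mature rate is
#' approached.
#'
#' @param age Stand age, years.
#' @param gamma_f0,gamma_f1 Juvenile/mature litterfall rate, month^-1.
#' @param t_gamma_f Ramp time scale, years.
#' @return Monthly litterfall fraction.
#' @export
litterfall_rate <- function(age, gamma_f0, gamma_f1, t_gamma_f) {
  if (gamma_f1 == gamma_f0) return(rep(gamma_f1, length(age)))
  kg <- log(1 + gamma_f1 / gamma_f0) / t_gamma_f
  gamma_f1 * gamma_f0 / (gamma_f0 + (gamma_f1 - gamma_f0) * exp(-kg * age))
}

#' Canopy light absorption and production for one month
#'
#' Beer-Lambert absorption of photosynthetically active radiation (half of
#' global shortwave), conversion to GPP through the modifier-reduced canopy
#' quantum efficiency, and NPP as the fixed fraction `y` of GPP.
#'
#' Unit chain: PAR (MJ m-2 month-1) -> absorbed PAR -> mol photons (4.6
#' mol/MJ) -> mol C (`alpha_c`, mol C / mol photons) -> g C (x12) -> g dry
#' matter (/0.5) -> Mg DM ha-1 (x0.01).
#'
#' @param wf Foliage biomass, Mg DM/ha.
#' @param age Stand age, years.
#' @param srad Monthly mean daily shortwave radiation, MJ m-2 day-1.
#' @param ndays Days in the month.
#' @param modifiers Modifier list from [compute_modifiers()].
#' @param params Parameter vector.
#' @return Named list `lai`, `apar` (MJ/m2), `gpp`, `npp` (Mg DM/ha/month).
#' @export
canopy_production <- function(wf, age, srad, ndays, modifiers, params) {
  p <- as.list(params)
  sla <- specific_leaf_area(age, p$sla0, p$sla1, p$t_sla)
  lai <- wf * sla * 0.1
  cover <- if (p$full_can_age > 0) min(age / p$full_can_age, 1) else 1
  par <- 0.5 * srad * ndays
  apar <- par * (1 - exp(-p$k * lai)) * cover
  alpha_eff <- p$alpha_c * modifiers$f_t * modifiers$f_frost *
    modifiers$f_nutr * modifiers$f_calpha * modifiers$phys_mod
  gpp <- alpha_eff * apar * MOL_PHOTON_PER_MJ_PAR * G_C_PER_MOL /
    CARBON_FRACTION * 0.01
  npp <- p$y * gpp
  list(lai = lai, apar = apar, gpp = gpp, npp = npp)
}

#' Partition NPP to foliage, roots and stems, with turnover
#'
#' Root fraction follows the 3-PG fertility/physiology form (decreasing with
#' `phys_mod` and soil fertility); the foliage:stem ratio is a power law of
#' mean DBH anchored at `pfs2` (2 cm) and `pfs20` (20 cm). The three
#' fractions sum to one exactly. Litterfall and root turnover losses are
#' returned alongside.
#'
#' @param npp NPP, Mg DM/ha/month (>= 0).
#' @param dbh Mean DBH, cm (for the foliage:stem ratio).
#' @param wf,wr Current foliage and root pools, Mg DM/ha.
#' @param age Stand age, years.
#' @param phys_mod Combined physiological modifier.
#' @param fr Site fertility rating.
#' @param params Parameter vector.
#' @return Named list: fractions `p_f`, `p_r`, `p_s`; pool increments `d_wf`,
#'   `d_wr`, `d_ws` (allocation minus turnover); losses `litterfall`,
#'   `root_turnover`.
#' @export
allocate_npp <- function(npp, dbh, wf, wr, age, phys_mod, fr, params) {
  if (npp < 0) stop("npp must be >= 0")
  p <- as.list(params)
  m <- p$m0 + (1 - p$m0) * fr
  p_r <- p$p_rx * p$p_rn / (p$p_rn + (p$p_rx - p$p_rn) * phys_mod * m)
  n_p <- log(p$pfs20 / p$pfs2) / log(10)
  a_p <- p$pfs2 / 2^n_p
  p_fs <- a_p * dbh^n_p
  p_s <- (1 - p_r) / (1 + p_fs)
  p_f <- 1 - p_r - p_s
  gamma_f <- litterfall_rate(age, p$gamma_f0, p$gamma_f1, p$t_gamma_f)
  litter <- gamma_f * wf
  root_to <- p$gamma_r * wr
  list(
    p_f = p_f, p_r = p_r, p_s = p_s,
    d_wf = npp * p_f - litter,
    d_wr = npp * p_r - root_to,
    d_ws = npp * p_s,
    litterfall = litter, root_turnover = root_to
  )
}
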