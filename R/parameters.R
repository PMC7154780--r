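# Species parameter set: the calibratable scalars of the simulator, grouped by
# submodel. Order is frozen (`param_names()`) because the compiled engine
# receives parameters as a bare numeric vector.

PARAM_NAMES <- c(
  # production
  "alpha_c", "y", "k", "full_can_age",
  # temperature / frost
  "t_min", "t_opt", "t_max", "k_frost",
  # water / air
  "coeff_cond", "sw_const", "sw_power", "max_cond", "min_cond", "lai_gcx",
  "bl_cond", "max_intcptn", "lai_max_intcptn", "soil_cond",
  # nutrition
  "fn0", "fnn", "m0",
  # age
  "max_age", "n_age", "r_age",
  # CO2
  "f_calpha700", "f_cg700",
  # allocation
  "pfs2", "pfs20", "p_rx", "p_rn",
  # turnover
  "gamma_f0", "gamma_f1", "t_gamma_f", "gamma_r",
  # mortality
  "w_sx1000", "thin_power", "m_f", "m_r", "m_s",
  # allometry / structure
  "a_ws", "n_ws", "a_h", "n_hb", "a_v", "n_vb", "sla0", "sla1", "t_sla",
  # phenology (months; 0/0 = evergreen)
  "leaf_grow", "leaf_fall"
)

#' Names and order of the species parameter vector
#'
#' The simulator consumes parameters as a named numeric vector in this fixed
#' order; all calibration machinery indexes into it by name.
#'
#' @return Character vector of parameter names.
#' @export
param_names <- function() PARAM_NAMES

#' Default species parameter sets
#'
#' Literature-style parameterisations for an evergreen montane conifer
#' ("picea"-like) and a deciduous broadleaf ("fagus"-like) species. Values are
#' representative of published 3-PG parameterisations for central European
#' forests; they are defaults for simulation and the centre of the synthetic
#' truth used in recovery experiments, not a fit to any particular dataset.
#'
#' @param species `"picea"` (evergreen conifer) or `"fagus"` (deciduous
#'   broadleaf).
#' @return Named numeric vector over [param_names()]. Units: cardinal
#'   temperatures degC; `coeff_cond` mbar^-1; conductances m/s; `w_sx1000` kg
#'   per tree at 1000 trees/ha; `a_ws` kg cm^-n_ws; `sla*` m2/kg; turnover
#'   rates month^-1; `t_gamma_f`, `t_sla`, ages in years.
#' @export
default_parameters <- function(species = c("picea", "fagus")) {
  species <- match.arg(species)
  p <- c(
    alpha_c = 0.045, y = 0.47, k = 0.5, full_can_age = 0,
    t_min = -2, t_opt = 15, t_max = 32, k_frost = 0.6,
    coeff_cond = 0.05, sw_const = 0.7, sw_power = 9,
    max_cond = 0.02, min_cond = 0, lai_gcx = 3.33,
    bl_cond = 0.2, max_intcptn = 0.15, lai_max_intcptn = 5, soil_cond = 0.002,
    fn0 = 0.6, fnn = 1, m0 = 0,
    max_age = 300, n_age = 4, r_age = 0.95,
    f_calpha700 = 1.4, f_cg700 = 0.7,
    pfs2 = 1.0, pfs20 = 0.30, p_rx = 0.8, p_rn = 0.25,
    gamma_f0 = 0.001, gamma_f1 = 0.015, t_gamma_f = 5, gamma_r = 0.015,
    w_sx1000 = 300, thin_power = 1.5, m_f = 0, m_r = 0.2, m_s = 0.2,
    a_ws = 0.077, n_ws = 2.5, a_h = 2.9, n_hb = 0.65, a_v = 1e-4, n_vb = 2.7,
    sla0 = 7, sla1 = 4, t_sla = 4,
    leaf_grow = 0, leaf_fall = 0
  )
  if (species == "fagus") {
    p[["alpha_c"]] <- 0.05
    p[["t_min"]] <- 0
    p[["t_opt"]] <- 18
    p[["t_max"]] <- 34
    p[["max_age"]] <- 250
    p[["pfs2"]] <- 0.9
    p[["pfs20"]] <- 0.35
    p[["w_sx1000"]] <- 350
    p[["a_ws"]] <- 0.09
    p[["n_ws"]] <- 2.45
    p[["sla0"]] <- 18
    p[["sla1"]] <- 14
    p[["gamma_f1"]] <- 0.02
    p[["leaf_grow"]] <- 5
    p[["leaf_fall"]] <- 11
  }
  p[PARAM_NAMES]
}

#' Validate a species parameter vector
#'
#' Checks completeness and the structural invariants the simulator relies on
#' (ordered cardinal temperatures, fractions in \[0,1\], positive allometric
#' and self-thinning coefficients).
#'
#' @param params Named numeric vector over [param_names()].
#' @return The parameter vector, invisibly, reordered to [param_names()].
#' @export
validate_parameters <- function(params) {
  missing <- setdiff(PARAM_NAMES, names(params))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  params <- params[PARAM_NAMES]
  if (anyNA(params)) stop("parameters contain NA")
  with(as.list(params), {
    if (!(t_min < t_opt && t_opt < t_max)) {
      stop("cardinal temperatures must satisfy t_min < t_opt < t_max")
    }
    if (y <= 0 || y >= 1) stop("y (NPP:GPP) must lie in (0,1)")
    for (nm in c("m_f", "m_r", "max_intcptn", "p_rx", "p_rn", "fn0", "m0")) {
      v <- get(nm)
      if (v < 0 || v > 1) stop(nm, " must lie in [0,1]")
    }
    if (thin_power <= 0) stop("thin_power must be > 0")
    if (w_sx1000 <= 0) stop("w_sx1000 must be > 0")
    if (sla0 <= 0 || sla1 <= 0) stop("specific leaf area must be > 0")
    if (a_ws <= 0 || n_ws <= 0) stop("stem allometry must be positive")
  })
  invisible(params)
}

#' Read a species parameter table
#'
#' Run mode expects columns `parameter,value`; calibration mode expects
#' `parameter,lit_min,lit_max` (and optionally `domain_min,domain_max`).
#'
#' @param path CSV file path.
#' @return Named numeric vector (run mode) or data.frame (calibration mode).
#' @export
read_parameter_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if ("value" %in% names(tab)) {
    return(setNames(tab$value, tab$parameter))
  }
  if (!all(c("lit_min", "lit_max") %in% names(tab))) {
    stop("parameter table needs either a 'value' or 'lit_min'/'lit_max' columns")
  }
  tab
}

#' Expand literature prior bounds by half their range
#'
#' Uniform prior bounds are widened from the literature minimum/maximum by
#' half the literature range on each side, then clipped to the parameter's
#' physical domain.
#'
#' @param lit_min,lit_max Literature bounds, `lit_min < lit_max`.
#' @param domain_min,domain_max Physical domain to clip to (default
#'   unbounded).
#' @return Numeric vector `c(min, max)` of expanded (clipped) bounds.
#' @export
expand_prior_bounds <- function(lit_min, lit_max,
                                domain_min = -Inf, domain_max = Inf) {
  if (!(lit_min < lit_max)) stop("lit_min must be strictly below lit_max")
  r <- lit_max - lit_min
  lo <- max(lit_min - r / 2, domain_min)
  hi <- min(lit_max + r / 2, domain_max)
  c(lo, hi)
}

#' Build a prior specification from a literature table
#'
#' Applies [expand_prior_bounds()] row-wise to a calibration-mode parameter
#' table.
#'
#' @param lit_table Data frame with `parameter`, `lit_min`, `lit_max` and
#'   optionally `domain_min`, `domain_max`.
#' @return Data frame with added `expanded_min`, `expanded_max`.
#' @export
make_prior_specification <- function(lit_table) {
  if (is.null(lit_table$domain_min)) lit_table$domain_min <- -Inf
  if (is.null(lit_table$domain_max)) lit_table$domain_max <- Inf
  b <- t(mapply(
    expand_prior_bounds,
    lit_table$lit_min, lit_table$lit_max,
    lit_table$domain_min, lit_table$domain_max
  ))
  lit_table$expanded_min <- b[, 1]
  lit_table$expanded_max <- b[, 2]
  lit_table
}
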