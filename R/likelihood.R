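# Robust Student-t likelihood and the simulator-backed log-posterior.

OBS_VARIABLES <- c("stem_biomass", "foliage_biomass", "root_biomass",
                   "n_trees", "dbh", "basal_area", "lai", "gpp")

OBS_OUTPUT_COLUMN <- c(
  stem_biomass = "ws", foliage_biomass = "wf", root_biomass = "wr",
  n_trees = "n_trees", dbh = "dbh", basal_area = "basal_area", lai = "lai",
  gpp = NA # trailing 12-month sum, handled specially
)

#' Names of the observable stand variables
#' @return Character vector of the eight observation variable codes.
#' @export
observation_variables <- function() OBS_VARIABLES

#' Robust Student-t log-likelihood
#'
#' Sum of location-scale Student-t log densities: location = prediction,
#' scale = the observed variable's error scale, degrees of freedom `u` shared
#' across variables. Heavy tails (small `u`) make the likelihood robust to
#' outlying observations.
#'
#' @param observed,predicted Aligned numeric vectors.
#' @param variable Character vector of variable codes aligned with the rows.
#' @param sigma_by_variable Named vector of error scales (> 0), one per
#'   variable present.
#' @param u Degrees of freedom (> 2).
#' @return Scalar log-likelihood.
#' @export
student_t_log_likelihood <- function(observed, predicted, variable,
                                     sigma_by_variable, u) {
  if (length(observed) != length(predicted)) {
    stop("need one prediction per observation")
  }
  if (anyNA(predicted)) {
    stop("missing prediction for row(s) ",
         paste(which(is.na(predicted)), collapse = ", "))
  }
  if (u <= 2) stop("u must exceed 2")
  s <- sigma_by_variable[variable]
  if (anyNA(s) || any(s <= 0)) stop("sigma must be > 0 for every variable")
  sum(dt((observed - predicted) / s, df = u, log = TRUE) - log(s))
}

# Precompute, for one calibration plot, the indices needed to pull
# predictions out of the simulator's monthly output table.
index_plot_observations <- function(plot) {
  key <- plot$climate$year * 12 + plot$climate$month
  obs <- plot$obs
  row <- match(obs$year * 12 + obs$month, key)
  if (anyNA(row)) stop("observation outside the plot's climate window")
  if (any(obs$variable == "gpp" & row < 12)) {
    stop("gpp observation needs >= 12 months of simulated history")
  }
  list(row = row, variable = obs$variable, value = obs$value)
}

# Extract the predicted value for each observation row from a monthly output
# table. gpp observations are trailing 12-month sums in Mg C/ha/yr.
extract_predictions <- function(out, idx) {
  pred <- numeric(length(idx$row))
  for (v in unique(idx$variable)) {
    sel <- idx$variable == v
    if (v == "gpp") {
      pred[sel] <- vapply(idx$row[sel], function(r) {
        sum(out$gpp[(r - 11):r]) * 0.5
      }, numeric(1))
    } else {
      pred[sel] <- out[[OBS_OUTPUT_COLUMN[[v]]]][idx$row[sel]]
    }
  }
  pred
}

#' Build the log-posterior for a set of calibration plots
#'
#' The returned closure maps a parameter vector theta (calibrated model
#' parameters, optionally followed by per-variable error scales and the
#' Student-t degrees of freedom) to an unnormalised log-posterior: uniform
#' priors contribute -Inf outside the bounds and a constant inside, so inside
#' the bounds the value is the Student-t log-likelihood summed over plots.
#' Each evaluation reruns the simulator per plot from its first observation
#' (no memoisation).
#'
#' @param plots List of calibration plots, each a list with `site`, `climate`
#'   (monthly data frame covering the observation window), `init_state`,
#'   `events`, `obs` (data frame `year`, `month`, `variable`, `value`).
#' @param theta_spec Data frame describing theta: columns `name`, `lower`,
#'   `upper`, `kind` (`"model"`, `"sigma"`, `"u"`); for `kind == "sigma"`,
#'   `name` is the observation variable code.
#' @param base_params Full parameter vector supplying every non-calibrated
#'   model parameter.
#' @param error Named list with fixed `sigma` (named vector) and `u`; entries
#'   are overridden by any sigma/u coordinates present in `theta_spec`.
#' @return Function `theta -> log posterior`.
#' @export
make_log_posterior <- function(plots, theta_spec, base_params,
                               error = list(sigma = NULL, u = 4)) {
  base_params <- validate_parameters(base_params)
  idx <- lapply(plots, index_plot_observations)
  kinds <- theta_spec$kind
  model_i <- which(kinds == "model")
  sigma_i <- which(kinds == "sigma")
  u_i <- which(kinds == "u")
  model_names <- theta_spec$name[model_i]
  sigma_names <- theta_spec$name[sigma_i]
  lower <- theta_spec$lower
  upper <- theta_spec$upper
  # static per-plot matrices for the compiled engine
  prep <- lapply(plots, function(pl) {
    list(
      cli = as.matrix(pl$climate[, c("year", "month", "tmin", "tmax", "prcp",
                                     "srad", "frost_days", "co2")]),
      si = c(pl$site$latitude, pl$site$asw_max, pl$site$fertility_rating),
      st = c(pl$init_state$age, pl$init_state$n_trees, pl$init_state$ws,
             pl$init_state$wf, pl$init_state$wr, pl$init_state$asw,
             pl$init_state$wf_debt),
      ev = if (is.null(pl$events) || !nrow(pl$events)) {
        matrix(numeric(0), 0, 5)
      } else {
        as.matrix(pl$events[order(pl$events$age),
                            c("age", "residual_stems", "frac_foliage",
                              "frac_root", "frac_stem")])
      }
    )
  })
  gpp_col <- which(OUTPUT_COLUMNS == "gpp")
  var_col <- vapply(OBS_VARIABLES[OBS_VARIABLES != "gpp"], function(v) {
    which(OUTPUT_COLUMNS == OBS_OUTPUT_COLUMN[[v]])
  }, integer(1))
  # flat extraction indices: a 2-column (row, col) matrix for the direct
  # variables and the trailing-12-month row windows for gpp
  flat <- lapply(idx, function(ix) {
    is_gpp <- ix$variable == "gpp"
    list(
      direct = cbind(ix$row[!is_gpp], var_col[ix$variable[!is_gpp]]),
      gpp_rows = ix$row[is_gpp],
      value = c(ix$value[!is_gpp], ix$value[is_gpp]),
      var = c(ix$variable[!is_gpp], ix$variable[is_gpp])
    )
  })
  obs_value <- unlist(lapply(flat, `[[`, "value"), use.names = FALSE)
  obs_var <- unlist(lapply(flat, `[[`, "var"), use.names = FALSE)
  np <- as.numeric(base_params)
  model_pos <- match(model_names, PARAM_NAMES)

  function(theta) {
    if (any(theta < lower | theta > upper)) return(-Inf)
    params <- np
    params[model_pos] <- theta[model_i]
    sigma <- error$sigma
    if (length(sigma_i)) sigma[sigma_names] <- theta[sigma_i]
    u <- if (length(u_i)) theta[u_i] else error$u
    pred <- vector("list", length(prep))
    for (k in seq_along(prep)) {
      pp <- prep[[k]]
      out <- tryCatch(
        run3pg_cpp(pp$cli, pp$si, params, pp$st, pp$ev),
        error = function(e) NULL
      )
      if (is.null(out)) return(-Inf)
      fl <- flat[[k]]
      g <- vapply(fl$gpp_rows, function(r) sum(out[(r - 11):r, gpp_col]) * 0.5,
                  numeric(1))
      pred[[k]] <- c(out[fl$direct], g)
    }
    p_all <- unlist(pred, use.names = FALSE)
    s <- sigma[obs_var]
    ll <- sum(dt((obs_value - p_all) / s, df = u, log = TRUE) - log(s))
    if (!is.finite(ll)) return(-Inf)
    ll
  }
}

#' Default theta specification for a reduced calibration
#'
#' The pre-registered identifiable subset (allometry, partitioning,
#' mortality) plus canopy quantum efficiency and mature specific leaf area:
#' the parameter groups stand-structure monitoring data constrain best.
#'
#' @param prior_spec Expanded prior table from [make_prior_specification()].
#' @param names Parameters to calibrate.
#' @return `theta_spec` data frame for [make_log_posterior()].
#' @export
reduced_theta_spec <- function(prior_spec,
                               names = c("alpha_c", "sla1",
                                         identifiable_subset())) {
  sel <- match(names, prior_spec$parameter)
  if (anyNA(sel)) stop("parameters missing from prior table")
  data.frame(
    name = names,
    lower = prior_spec$expanded_min[sel],
    upper = prior_spec$expanded_max[sel],
    kind = "model",
    stringsAsFactors = FALSE
  )
}

#' The pre-registered identifiable parameter subset
#'
#' Allometry, biomass-partitioning and stem-mortality parameters: the groups
#' for which stand-structure observations are most informative.
#'
#' @return Character vector of parameter names.
#' @export
identifiable_subset <- function() {
  c("a_ws", "n_ws", "pfs2", "pfs20", "p_rx", "p_rn", "w_sx1000", "thin_power")
}
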