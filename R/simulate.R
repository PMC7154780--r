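# The monthly stepping engine. `step_month()` is the documented R stage
# chain; `run_simulation()` dispatches either to it or to the compiled
# translation (`engine = "cpp"`, the default) which is pinned to the R chain
# by tests.

#' Construct a stand state
#'
#' @param age Stand age, years (fractional; advances by 1/12 per month).
#' @param n_trees Stems per hectare.
#' @param ws,wf,wr Stem/foliage/root biomass, Mg DM/ha.
#' @param asw Available soil water, mm.
#' @param wf_debt Dormant-season foliage store for deciduous species,
#'   Mg DM/ha (0 for evergreens).
#' @return A list with class `stand_state`.
#' @export
new_stand_state <- function(age, n_trees, ws, wf, wr, asw, wf_debt = 0) {
  stopifnot(age >= 0, n_trees >= 0, ws >= 0, wf >= 0, wr >= 0, asw >= 0)
  structure(
    list(age = age, n_trees = n_trees, ws = ws, wf = wf, wr = wr,
         asw = asw, wf_debt = wf_debt),
    class = "stand_state"
  )
}

#' Advance a stand by one month
#'
#' Fixed stage order: deciduous phenology, environmental modifiers, canopy
#' production, NPP allocation and turnover, self-thinning mortality, water
#' balance, management events due this month, derived attributes; age
#' advances by 1/12.
#'
#' @param state Stand state from [new_stand_state()].
#' @param climate One-month record: list with `year`, `month`, `tmin`,
#'   `tmax`, `prcp`, `srad`, `frost_days`, `co2`.
#' @param site Site list: `latitude`, `asw_max`, `fertility_rating` (and
#'   optionally `elevation`).
#' @param params Parameter vector.
#' @param events Data frame of thinning events due this month (may be NULL).
#' @return List `state` (updated) and `out` (named numeric of monthly fluxes
#'   and derived attributes).
#' @export
step_month <- function(state, climate, site, params, events = NULL) {
  p <- as.list(params)
  ndays <- days_in_month(climate$year, climate$month)

  # 1. phenology (deciduous foliage debt)
  if (p$leaf_grow > 0) {
    if (climate$month == p$leaf_grow) {
      state$wf <- state$wf + state$wf_debt
      state$wf_debt <- 0
    }
    if (climate$month == p$leaf_fall) {
      state$wf_debt <- state$wf_debt + state$wf
      state$wf <- 0
    }
  }

  # 2. modifiers (start-of-month soil water and age)
  mods <- compute_modifiers(climate, state$asw, state$age, site, p, ndays)

  # 3. production
  prod <- canopy_production(state$wf, state$age, climate$srad, ndays, mods, p)

  # 4. allocation + turnover (needs mean DBH from the current stem pool)
  n_died <- 0
  if (state$n_trees > 0) {
    attr0 <- derive_stand_attributes(state$n_trees, state$ws, state$wf,
                                     state$age, p)
    alloc <- allocate_npp(prod$npp, attr0$dbh, state$wf, state$wr, state$age,
                          mods$phys_mod, site$fertility_rating, p)
    state$wf <- max(state$wf + alloc$d_wf, 0)
    state$wr <- max(state$wr + alloc$d_wr, 0)
    state$ws <- max(state$ws + alloc$d_ws, 0)

    # 5. density-dependent mortality
    mort <- density_dependent_mortality(state$n_trees, state$ws, state$wf,
                                        state$wr, p)
    n_died <- mort$n_died
    state$n_trees <- mort$n_trees
    state$ws <- mort$ws
    state$wf <- mort$wf
    state$wr <- mort$wr
  }

  # 6. water balance (uses start-of-month LAI)
  gc <- canopy_conductance(prod$lai, mods, p)
  et <- evapotranspiration(climate, prod$lai, gc, state$asw, site$latitude,
                           climate$month, ndays, p)
  sw <- update_soil_water(state$asw, climate$prcp, et$interception,
                          et$transpiration, et$soil_evap, site$asw_max)
  state$asw <- sw$asw

  # 7. management due this month
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      state <- apply_management(state, as.list(events[i, ]))
    }
  }

  # 8. age and derived attributes
  state$age <- state$age + 1 / 12
  attr1 <- derive_stand_attributes(state$n_trees, state$ws, state$wf,
                                   state$age, p)

  out <- c(
    year = climate$year, month = climate$month, age = state$age,
    n_trees = state$n_trees, ws = state$ws, wf = state$wf, wr = state$wr,
    asw = state$asw, lai = attr1$lai, dbh = attr1$dbh, height = attr1$height,
    basal_area = attr1$basal_area, volume = attr1$volume,
    gpp = prod$gpp, npp = prod$npp,
    transpiration = et$transpiration, soil_evap = et$soil_evap,
    interception = et$interception, runoff = sw$runoff, clip = sw$clip,
    n_died = n_died
  )
  list(state = state, out = out)
}

OUTPUT_COLUMNS <- c(
  "year", "month", "age", "n_trees", "ws", "wf", "wr", "asw", "lai", "dbh",
  "height", "basal_area", "volume", "gpp", "npp", "transpiration",
  "soil_evap", "interception", "runoff", "clip", "n_died"
)

#' Run the simulator over a monthly climate series
#'
#' Deterministic given inputs. The compiled engine (`engine = "cpp"`) is an
#' exact translation of the [step_month()] stage chain; the R engine is the
#' readable reference. Events whose trigger age falls within a month are
#' applied in that month, after mortality.
#'
#' @param site Site list: `latitude`, `asw_max`, `fertility_rating`,
#'   optionally `elevation`.
#' @param climate Data frame of consecutive months with columns `year`,
#'   `month`, `tmin`, `tmax`, `prcp`, `srad`, `frost_days`, `co2`.
#' @param params Parameter vector.
#' @param initial_state Stand state from [new_stand_state()].
#' @param events Thinning schedule from [management_schedule()] (ages in
#'   years), or NULL.
#' @param horizon Number of months to run (default: all of `climate`).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return Data frame, one row per month, columns as in the package output
#'   dictionary (biomass Mg DM/ha, fluxes Mg DM/ha/month, water mm/month).
#' @export
run_simulation <- function(site, climate, params, initial_state,
                           events = NULL, horizon = nrow(climate),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  params <- validate_parameters(params)
  if (horizon > nrow(climate)) {
    stop("climate series shorter than requested horizon")
  }
  if (horizon > 1) {
    mo <- climate$month[1:horizon]
    yr <- climate$year[1:horizon]
    jump <- diff(yr * 12 + mo)
    if (any(jump != 1)) {
      bad <- which(jump != 1)[1]
      stop(sprintf("climate gap after %d-%02d", yr[bad], mo[bad]))
    }
  }
  if (horizon == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = length(OUTPUT_COLUMNS),
                  dimnames = list(NULL, OUTPUT_COLUMNS))
    return(as.data.frame(out))
  }
  ev <- if (is.null(events) || !nrow(events)) {
    matrix(numeric(0), 0, 5)
  } else {
    as.matrix(events[order(events$age),
                     c("age", "residual_stems", "frac_foliage", "frac_root",
                       "frac_stem")])
  }
  if (engine == "cpp") {
    cli <- as.matrix(climate[1:horizon, c("year", "month", "tmin", "tmax",
                                          "prcp", "srad", "frost_days",
                                          "co2")])
    st <- c(initial_state$age, initial_state$n_trees, initial_state$ws,
            initial_state$wf, initial_state$wr, initial_state$asw,
            initial_state$wf_debt)
    si <- c(site$latitude, site$asw_max, site$fertility_rating)
    out <- run3pg_cpp(cli, si, as.numeric(params), st, ev)
    colnames(out) <- OUTPUT_COLUMNS
    return(as.data.frame(out))
  }
  state <- initial_state
  out <- matrix(NA_real_, horizon, length(OUTPUT_COLUMNS),
                dimnames = list(NULL, OUTPUT_COLUMNS))
  ev_i <- 1
  for (i in 1:horizon) {
    cm <- as.list(climate[i, ])
    age_end <- state$age + 1 / 12
    due <- NULL
    while (ev_i <= nrow(ev) && ev[ev_i, 1] <= age_end + 1e-9) {
      due <- rbind(due, ev[ev_i, , drop = FALSE])
      ev_i <- ev_i + 1
    }
    due_df <- if (is.null(due)) NULL else {
      data.frame(age = due[, 1], residual_stems = due[, 2],
                 frac_foliage = due[, 3], frac_root = due[, 4],
                 frac_stem = due[, 5])
    }
    stepped <- step_month(state, cm, site, params, due_df)
    state <- stepped$state
    out[i, ] <- stepped$out[OUTPUT_COLUMNS]
  }
  as.data.frame(out)
}

#' Aggregate a monthly output table to calendar years
#'
#' Fluxes are summed, states are taken at the last month of each year.
#'
#' @param monthly Output of [run_simulation()].
#' @return Data frame with one row per calendar year; `npp` and `gpp` are
#'   annual sums in Mg DM/ha/yr, `npp_c` the NPP in Mg C/ha/yr (carbon
#'   fraction 0.5).
#' @export
annual_aggregate <- function(monthly) {
  yrs <- unique(monthly$year)
  do.call(rbind, lapply(yrs, function(y) {
    m <- monthly[monthly$year == y, ]
    last <- m[nrow(m), ]
    data.frame(
      year = y, n_months = nrow(m), age = last$age, n_trees = last$n_trees,
      ws = last$ws, wf = last$wf, wr = last$wr, asw = last$asw,
      lai = last$lai, dbh = last$dbh, basal_area = last$basal_area,
      gpp = sum(m$gpp), npp = sum(m$npp), npp_c = sum(m$npp) * 0.5,
      transpiration = sum(m$transpiration), runoff = sum(m$runoff)
    )
  }))
}
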