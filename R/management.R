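# Management (thinning) events.

#' Apply a thinning event to a stand state
#'
#' Stem number is set to the residual stocking; each removed tree carries the
#' event's fractions of the mean tree's foliage/root/stem pools (fractions
#' above 1 encode removal of above-average trees). A residual above the
#' current stocking is a no-op with a warning.
#'
#' @param state Stand state list (see [new_stand_state()]).
#' @param event List or one-row data.frame with `residual_stems`,
#'   `frac_foliage`, `frac_root`, `frac_stem`.
#' @return Updated stand state.
#' @export
apply_management <- function(state, event) {
  if (event$residual_stems > state$n_trees) {
    warning("residual stocking above current stocking; thinning skipped")
    return(state)
  }
  removed <- state$n_trees - event$residual_stems
  if (removed <= 0) return(state)
  frac <- removed / state$n_trees
  state$ws <- max(state$ws * (1 - event$frac_stem * frac), 0)
  state$wf <- max(state$wf * (1 - event$frac_foliage * frac), 0)
  state$wr <- max(state$wr * (1 - event$frac_root * frac), 0)
  state$n_trees <- event$residual_stems
  state
}

#' Construct a management schedule
#'
#' @param age Stand ages (years) at which thinnings occur.
#' @param residual_stems Residual stocking (trees/ha) after each thinning.
#' @param frac_foliage,frac_root,frac_stem Fractions of a mean tree's pools
#'   carried by each removed tree (default 1: thinning of average trees).
#' @return Data frame sorted by age.
#' @export
management_schedule <- function(age, residual_stems, frac_foliage = 1,
                                frac_root = 1, frac_stem = 1) {
  ev <- data.frame(
    age = age, residual_stems = residual_stems,
    frac_foliage = frac_foliage, frac_root = frac_root,
    frac_stem = frac_stem
  )
  ev[order(ev$age), , drop = FALSE]
}
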