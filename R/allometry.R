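# Allometric conversion of biomass pools into stand attributes, and the
# inverse used to initialise a stand from structural observations.

#' Derive stand attributes from biomass pools
#'
#' Mean DBH is obtained by inverting the stem-mass allometry
#' `ws_tree_kg = a_ws * dbh^n_ws`; height and volume follow their own power
#' laws of DBH; basal area is exact geometry.
#'
#' @param n_trees Stems per hectare.
#' @param ws Stem biomass, Mg DM/ha.
#' @param wf Foliage biomass, Mg DM/ha.
#' @param age Stand age, years.
#' @param params Parameter vector.
#' @return Named list `dbh` (cm), `height` (m), `basal_area` (m2/ha),
#'   `volume` (m3/ha), `lai`. All zero when `n_trees == 0`.
#' @export
derive_stand_attributes <- function(n_trees, ws, wf, age, params) {
  p <- as.list(params)
  sla <- specific_leaf_area(age, p$sla0, p$sla1, p$t_sla)
  lai <- wf * sla * 0.1
  if (n_trees <= 0) {
    return(list(dbh = 0, height = 0, basal_area = 0, volume = 0, lai = lai))
  }
  ws_tree <- ws * 1000 / n_trees # kg per mean tree
  dbh <- (ws_tree / p$a_ws)^(1 / p$n_ws)
  list(
    dbh = dbh,
    height = p$a_h * dbh^p$n_hb,
    basal_area = pi * (dbh / 200)^2 * n_trees,
    volume = p$a_v * dbh^p$n_vb * n_trees,
    lai = lai
  )
}

#' Initialise biomass pools from structural observations
#'
#' When only structure (stems/ha and mean DBH) is observed, the stem pool is
#' recovered through the stem-mass allometry and foliage/roots are set from
#' typical pool ratios at that stem mass.
#'
#' @param n_trees Stems per hectare.
#' @param dbh Mean DBH, cm.
#' @param params Parameter vector.
#' @param wf_ratio,wr_ratio Foliage and root pools as fractions of the stem
#'   pool (defaults 0.06 and 0.20).
#' @return Named list `ws`, `wf`, `wr` in Mg DM/ha.
#' @export
pools_from_structure <- function(n_trees, dbh, params,
                                 wf_ratio = 0.06, wr_ratio = 0.20) {
  p <- as.list(params)
  ws <- p$a_ws * dbh^p$n_ws * n_trees / 1000
  list(ws = ws, wf = ws * wf_ratio, wr = ws * wr_ratio)
}
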