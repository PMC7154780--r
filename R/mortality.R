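# Density-dependent (self-thinning) mortality after Yoda's -3/2 law.

#' Self-thinning mortality for one month
#'
#' The maximum permitted mean stem mass is
#' `w_sx = w_sx1000 * (1000 / n)^thin_power` (kg/tree). When the current mean
#' stem mass exceeds it, the smallest (continuous) number of trees is removed
#' such that the constraint holds after removal, each dying tree carrying
#' `m_f`, `m_r`, `m_s` fractions of the mean tree's foliage/root/stem pools.
#' The removal count is solved by bisection to 1e-8 trees/ha.
#'
#' @param n_trees Stems per hectare (> 0).
#' @param ws,wf,wr Stem/foliage/root pools, Mg DM/ha.
#' @param params Parameter vector (uses `w_sx1000`, `thin_power`, `m_f`,
#'   `m_r`, `m_s`).
#' @return Named list `n_died` plus updated `n_trees`, `ws`, `wf`, `wr`.
#' @export
density_dependent_mortality <- function(n_trees, ws, wf, wr, params) {
  p <- as.list(params)
  if (n_trees <= 0) stop("n_trees must be > 0")
  # permitted stand-level stem mass at the current stocking (same expression
  # as the compiled engine's cached threshold)
  thr_ws <- p$w_sx1000 * (1000 / n_trees)^p$thin_power * n_trees / 1000
  if (ws <= thr_ws) {
    return(list(n_died = 0, n_trees = n_trees, ws = ws, wf = wf, wr = wr))
  }
  nd <- solve_thinning(n_trees, ws, p$w_sx1000, p$thin_power, p$m_s)
  if (nd <= 0) {
    return(list(n_died = 0, n_trees = n_trees, ws = ws, wf = wf, wr = wr))
  }
  frac <- nd / n_trees
  list(
    n_died = nd,
    n_trees = n_trees - nd,
    ws = ws * (1 - p$m_s * frac),
    wf = wf * (1 - p$m_f * frac),
    wr = wr * (1 - p$m_r * frac)
  )
}

# Root of the self-thinning constraint in log space. With x the residual
# stocking, phi(x) = log(mean stem mass at x) - log(permitted mass at x) is
# smooth and crosses zero once on (0, n]; a bracketed Newton iteration
# converges in a handful of steps and falls back to bisection whenever a
# Newton step leaves the bracket. Returns trees/ha to remove (0 if the
# stand is below the boundary). Mirrored exactly in the compiled engine.
solve_thinning <- function(n, ws, w_sx1000, thin_power, m_s) {
  c0 <- log(1000 * ws) - log(w_sx1000) - thin_power * log(1000)
  phi <- function(x) {
    log((1 - m_s) + m_s * x / n) + (thin_power - 1) * log(x) + c0
  }
  dphi <- function(x) {
    (m_s / n) / ((1 - m_s) + m_s * x / n) + (thin_power - 1) / x
  }
  if (phi(n) <= 0) return(0)
  lo <- 0.05 * n
  hi <- n
  if (phi(lo) > 0) {
    stop("mortality solver did not bracket a solution: n=", n, " ws=", ws,
         " (stand beyond the representable thinning range)")
  }
  x <- n
  for (i in 1:100) {
    step <- phi(x) / dphi(x)
    x_new <- x - step
    if (!(x_new > lo && x_new < hi)) x_new <- (lo + hi) / 2
    if (phi(x_new) > 0) hi <- x_new else lo <- x_new
    if (abs(x_new - x) < 1e-11 || (hi - lo) < 1e-11) {
      x <- x_new
      break
    }
    x <- x_new
  }
  n - x
}
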