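# Posterior-predictive simulation and skill statistics.

#' Posterior-predictive distributions per plot
#'
#' Draws parameter vectors with replacement from the pooled posterior
#' samples, reruns the simulator per draw and plot, and summarises the
#' predictive distribution at every observation row.
#'
#' @param ensemble A `posterior_ensemble`.
#' @param plots Calibration plots (see [make_log_posterior()]).
#' @param base_params Full parameter vector for non-calibrated entries.
#' @param n_draws Number of posterior draws (default 1000).
#' @param seed Integer seed.
#' @return List: `draws` (matrix observations x draws), `obs` (data frame of
#'   plot_id/variable/value aligned with rows), `summary` (per-row predictive
#'   median and 95% interval).
#' @export
posterior_predictive <- function(ensemble, plots, base_params,
                                 n_draws = 1000, seed = NULL) {
  pool <- pooled_samples(ensemble)
  model_names <- ensemble$theta_spec$name[ensemble$theta_spec$kind == "model"]
  idx <- lapply(plots, index_plot_observations)
  obs <- do.call(rbind, lapply(seq_along(plots), function(k) {
    data.frame(plot_id = plots[[k]]$plot_id,
               variable = idx[[k]]$variable,
               value = idx[[k]]$value, stringsAsFactors = FALSE)
  }))
  draws_idx <- with_seed(seed, sample.int(nrow(pool), n_draws, replace = TRUE))
  pred <- matrix(NA_real_, nrow(obs), n_draws)
  base_params <- validate_parameters(base_params)
  for (j in seq_len(n_draws)) {
    params <- base_params
    params[model_names] <- pool[draws_idx[j], model_names]
    row0 <- 0
    for (k in seq_along(plots)) {
      pl <- plots[[k]]
      out <- run_simulation(pl$site, pl$climate, params, pl$init_state,
                            pl$events)
      pred[row0 + seq_along(idx[[k]]$row), j] <-
        extract_predictions(out, idx[[k]])
      row0 <- row0 + length(idx[[k]]$row)
    }
  }
  qs <- t(apply(pred, 1, quantile, probs = c(0.025, 0.5, 0.975)))
  list(
    draws = pred, obs = obs,
    summary = cbind(obs, data.frame(pred_lo = qs[, 1], pred_median = qs[, 2],
                                    pred_hi = qs[, 3]))
  )
}

#' Predictive skill statistics: pBias, RMSE, NRMSE
#'
#' For each posterior draw the statistics are computed per plot
#' (`pBias = 100 * sum(pred - obs) / sum(obs)`, RMSE, and
#' `NRMSE = 100 * RMSE / mean(obs)`), then averaged over plots; the median
#' and 95% interval over draws are reported per variable. The plot-first
#' averaging order matters and is pinned by tests. Plots with zero observed
#' mean are excluded from NRMSE with a warning.
#'
#' @param obs Data frame with `plot_id`, `variable`, `value`, aligned with
#'   the rows of `predicted`.
#' @param predicted Matrix (observations x draws) or vector of predictions.
#' @return Data frame: `variable`, `statistic`, `median`, `q2.5`, `q97.5`.
#' @export
prediction_statistics <- function(obs, predicted) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, ncol = 1)
  if (nrow(predicted) != nrow(obs)) stop("rows of predicted must align with obs")
  res <- list()
  for (v in unique(obs$variable)) {
    sel <- which(obs$variable == v)
    plots <- unique(obs$plot_id[sel])
    stat_draws <- vapply(seq_len(ncol(predicted)), function(j) {
      per_plot <- vapply(plots, function(pid) {
        rows <- sel[obs$plot_id[sel] == pid]
        o <- obs$value[rows]
        p <- predicted[rows, j]
        pbias <- 100 * sum(p - o) / sum(o)
        rmse <- sqrt(mean((p - o)^2))
        nrmse <- if (mean(o) > 0) 100 * rmse / mean(o) else NA_real_
        c(pbias, rmse, nrmse)
      }, numeric(3))
      if (anyNA(per_plot[3, ])) {
        warning("plot with zero observed mean excluded from NRMSE for ", v)
      }
      c(mean(per_plot[1, ]), mean(per_plot[2, ]),
        mean(per_plot[3, ], na.rm = TRUE))
    }, numeric(3))
    qs <- function(i) quantile(stat_draws[i, ], c(0.5, 0.025, 0.975))
    for (i in seq_along(c("pBias", "RMSE", "NRMSE"))) {
      q <- qs(i)
      res[[length(res) + 1]] <- data.frame(
        variable = v, statistic = c("pBias", "RMSE", "NRMSE")[i],
        median = q[[1]], q2.5 = q[[2]], q97.5 = q[[3]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}

#' Split plots into calibration and validation halves
#'
#' Seeded permutation split by plot (never by observation row); with an odd
#' number of plots the extra plot goes to the calibration half.
#'
#' @param plot_ids Vector of plot identifiers (>= 2).
#' @param seed Integer seed.
#' @return List `calibration`, `validation`.
#' @export
cross_validation_split <- function(plot_ids, seed) {
  if (length(plot_ids) < 2) stop("need at least 2 plots")
  perm <- with_seed(seed, sample(plot_ids))
  n_cal <- ceiling(length(plot_ids) / 2)
  list(calibration = perm[seq_len(n_cal)],
       validation = perm[-seq_len(n_cal)])
}
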