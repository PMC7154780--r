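# Differential-evolution MCMC with a past-state archive (DEzs) and snooker
# updates, after ter Braak & Vrugt (2008).

# One DEzs proposal from the current point and the archive. Returns the
# proposal and the log of any asymmetry correction (snooker moves need one).
dezs_propose <- function(x, z, d, gamma, eps_sd, snooker) {
  nz <- nrow(z)
  if (snooker) {
    zi <- sample.int(nz, 3)
    zp <- z[zi[1], ]
    dvec <- x - zp
    denom <- sum(dvec^2)
    if (denom < 1e-300) {
      # degenerate projection direction: straight DE move instead
      return(dezs_propose(x, z, d, gamma, eps_sd, FALSE))
    }
    gs <- runif(1, 1.2, 2.2)
    proj <- sum((z[zi[2], ] - z[zi[3], ]) * dvec) / denom
    xp <- x + gs * proj * dvec
    corr <- (d - 1) * (log(sqrt(sum((xp - zp)^2))) - log(sqrt(denom)))
    list(x = xp, log_corr = corr)
  } else {
    ab <- sample.int(nz, 2) # without replacement: a != b guaranteed
    xp <- x + gamma * (z[ab[1], ] - z[ab[2], ]) + rnorm(d, 0, eps_sd)
    list(x = xp, log_corr = 0)
  }
}

#' DEzs MCMC sampler
#'
#' Differential-evolution Markov chain Monte Carlo with proposals generated
#' from an archive of past states ("z"), occasional mode-jumping steps
#' (`gamma = 1`), small jitter, and snooker updates. Multiple internal chains
#' share the archive.
#'
#' @param log_post Function mapping a parameter vector to the log posterior
#'   (-Inf outside the support).
#' @param lower,upper Numeric prior bounds (used for archive initialisation,
#'   jitter scaling and bound rejection).
#' @param iterations Total number of posterior evaluations, split across
#'   chains.
#' @param n_chains Number of internal chains sharing the archive (default 3).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param snooker_prob Probability of a snooker update (default 0.1).
#' @param gamma_jump_every A plain `gamma = 1` mode-jumping step every this
#'   many generations (default 10).
#' @param archive_every Append the chain states to the archive every this
#'   many generations (default 10).
#' @param init Optional matrix (`n_chains` x d) of starting points; default
#'   prior draws.
#' @return List with `chains` (list of generation x d matrices), `log_post`
#'   (matrix generations x chains), `acceptance` (per chain), `z` (final
#'   archive), and the settings.
#' @export
dezs_sample <- function(log_post, lower, upper, iterations, n_chains = 3,
                        seed = NULL, snooker_prob = 0.1,
                        gamma_jump_every = 10, archive_every = 10,
                        init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  gens <- max(2, floor(iterations / n_chains))
  gamma0 <- 2.38 / sqrt(2 * d)
  eps_sd <- 1e-6 * (upper - lower)
  with_seed(seed, {
    n_z0 <- max(10 * d, n_chains + 3)
    z <- matrix(runif(n_z0 * d, rep(lower, each = n_z0),
                      rep(upper, each = n_z0)), n_z0, d)
    x <- if (is.null(init)) {
      matrix(runif(n_chains * d, rep(lower, each = n_chains),
                   rep(upper, each = n_chains)), n_chains, d)
    } else {
      init
    }
    lp <- apply(x, 1, log_post)
    # grow-once archive storage
    cap <- n_z0 + (gens %/% archive_every + 1) * n_chains
    z_store <- matrix(NA_real_, cap, d)
    z_store[1:n_z0, ] <- z
    n_z <- n_z0
    chains <- lapply(seq_len(n_chains), function(i) matrix(NA_real_, gens, d))
    lp_store <- matrix(NA_real_, gens, n_chains)
    acc <- numeric(n_chains)
    for (g in seq_len(gens)) {
      gamma <- if (g %% gamma_jump_every == 0) 1 else gamma0
      for (i in seq_len(n_chains)) {
        snooker <- runif(1) < snooker_prob
        prop <- dezs_propose(x[i, ], z_store[1:n_z, , drop = FALSE], d,
                             gamma, eps_sd, snooker)
        lp_p <- if (any(prop$x < lower | prop$x > upper)) {
          -Inf
        } else {
          log_post(prop$x)
        }
        if (is.finite(lp_p) || is.finite(lp[i])) {
          if (log(runif(1)) < lp_p - lp[i] + prop$log_corr) {
            x[i, ] <- prop$x
            lp[i] <- lp_p
            acc[i] <- acc[i] + 1
          }
        }
        chains[[i]][g, ] <- x[i, ]
        lp_store[g, i] <- lp[i]
      }
      if (g %% archive_every == 0) {
        z_store[(n_z + 1):(n_z + n_chains), ] <- x
        n_z <- n_z + n_chains
      }
    }
    list(
      chains = chains, log_post = lp_store, acceptance = acc / gens,
      z = z_store[1:n_z, , drop = FALSE],
      settings = list(iterations = iterations, n_chains = n_chains,
                      generations = gens, seed = seed,
                      snooker_prob = snooker_prob,
                      gamma_jump_every = gamma_jump_every,
                      archive_every = archive_every)
    )
  })
}

#' Run a full multi-run DEzs calibration
#'
#' Independent DEzs runs (each with its own internal chains and archive, and
#' a distinct sub-seed), burn-in discarding, thinning, and Gelman-Rubin
#' convergence diagnostics over all post-burn-in chains.
#'
#' @param log_post Log-posterior closure, e.g. from [make_log_posterior()].
#' @param theta_spec Theta description (see [make_log_posterior()]); its
#'   `lower`/`upper` columns define the uniform prior box.
#' @param settings List: `n_runs` (default 3), `n_chains` (default 3),
#'   `iterations` (posterior evaluations per run), `burn_in` (fraction,
#'   default 0.5), `max_retained` per chain (default 1e4).
#' @param seed Integer seed (mandatory).
#' @return Object of class `posterior_ensemble`: `samples` (list of
#'   post-burn-in, thinned chain matrices across all runs), `psrf`
#'   (multivariate and per-parameter), `acceptance`, `theta_spec`,
#'   `settings`, `seed`.
#' @export
run_calibration <- function(log_post, theta_spec, settings = list(),
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  s <- utils::modifyList(
    list(n_runs = 3, n_chains = 3, iterations = 20000, burn_in = 0.5,
         max_retained = 1e4),
    settings
  )
  lower <- theta_spec$lower
  upper <- theta_spec$upper
  runs <- lapply(seq_len(s$n_runs), function(r) {
    dezs_sample(log_post, lower, upper, iterations = s$iterations,
                n_chains = s$n_chains, seed = (seed + 7919 * r) %% 2^31)
  })
  chains <- list()
  for (r in seq_along(runs)) {
    for (i in seq_len(s$n_chains)) {
      ch <- runs[[r]]$chains[[i]]
      keep <- seq(floor(nrow(ch) * s$burn_in) + 1, nrow(ch))
      thin <- max(1, ceiling(length(keep) / s$max_retained))
      ch <- ch[keep[seq(1, length(keep), by = thin)], , drop = FALSE]
      colnames(ch) <- theta_spec$name
      chains[[length(chains) + 1]] <- ch
    }
  }
  psrf <- gelman_rubin_psrf(chains)
  structure(
    list(
      samples = chains, psrf = psrf,
      acceptance = vapply(runs, function(r) mean(r$acceptance), numeric(1)),
      theta_spec = theta_spec, settings = s, seed = seed
    ),
    class = "posterior_ensemble"
  )
}

#' Pool all retained samples of an ensemble into one matrix
#' @param ensemble A `posterior_ensemble`.
#' @return Matrix (samples x parameters).
#' @export
pooled_samples <- function(ensemble) {
  do.call(rbind, ensemble$samples)
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  n <- sum(vapply(x$samples, nrow, integer(1)))
  cat("posterior_ensemble:", length(x$samples), "chains,", n,
      "retained samples,", ncol(x$samples[[1]]), "parameters\n")
  cat("multivariate PSRF:", round(x$psrf$multivariate, 4), "\n")
  invisible(x)
}
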