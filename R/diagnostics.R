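# Convergence diagnostics and Monte Carlo error estimates.

#' Gelman-Rubin convergence diagnostics
#'
#' Per-parameter potential scale reduction factors (Gelman-Rubin) and the
#' Brooks-Gelman multivariate PSRF computed over a set of equal-length
#' post-burn-in chains. Degenerate (zero-variance) parameter dimensions
#' return 1 with a warning.
#'
#' @param chains List of matrices (iterations x parameters), one per chain;
#'   at least 2 chains of at least 10 samples.
#' @return List `multivariate` (scalar) and `per_parameter` (named vector).
#' @export
gelman_rubin_psrf <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- min(vapply(chains, nrow, integer(1)))
  if (n < 10) stop("need at least 10 post-burn-in samples per chain")
  chains <- lapply(chains, function(ch) ch[seq_len(n), , drop = FALSE])
  d <- ncol(chains[[1]])
  means <- matrix(vapply(chains, colMeans, numeric(d)), m, d,
                  byrow = TRUE)                                # m x d
  vars <- matrix(vapply(chains, function(ch) apply(ch, 2, var), numeric(d)),
                 m, d, byrow = TRUE)
  w <- colMeans(vars)                                          # within
  b_over_n <- apply(means, 2, var)                             # between / n
  degenerate <- w <= 0
  if (any(degenerate)) {
    warning("zero within-chain variance for ",
            paste(colnames(chains[[1]])[degenerate], collapse = ", "),
            "; PSRF set to 1")
  }
  psrf <- rep(1, d)
  ok <- !degenerate
  psrf[ok] <- sqrt((n - 1) / n + ((m + 1) / m) * b_over_n[ok] / w[ok])
  names(psrf) <- colnames(chains[[1]])

  # Brooks-Gelman multivariate version: largest eigenvalue of W^-1 B/n
  w_mat <- matrix(0, d, d)
  for (ch in chains) w_mat <- w_mat + cov(ch)
  w_mat <- w_mat / m
  b_mat <- cov(means) # = B/n
  mpsrf <- if (all(degenerate)) {
    1
  } else {
    lambda <- tryCatch({
      max(Re(eigen(solve(w_mat + diag(1e-12, d), b_mat),
                   only.values = TRUE)$values))
    }, error = function(e) NA_real_)
    if (is.na(lambda)) max(psrf) else sqrt((n - 1) / n + ((m + 1) / m) * lambda)
  }
  list(multivariate = mpsrf, per_parameter = psrf)
}

#' @importFrom stats cov
NULL

#' Batch-means Monte Carlo standard error
#'
#' @param x Numeric vector of correlated MCMC draws.
#' @param n_batches Number of batches (default 30).
#' @return Estimated standard error of the mean of `x`.
#' @export
mcmc_standard_error <- function(x, n_batches = 30) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  sd(bm) / sqrt(n_batches)
}

#' Marginal credible intervals from an ensemble
#'
#' @param ensemble A `posterior_ensemble`.
#' @param level Credible level (default 0.9).
#' @return Data frame `parameter`, `lower`, `median`, `upper`.
#' @export
credible_intervals <- function(ensemble, level = 0.9) {
  x <- pooled_samples(ensemble)
  a <- (1 - level) / 2
  q <- t(apply(x, 2, quantile, probs = c(a, 0.5, 1 - a)))
  data.frame(parameter = colnames(x), lower = q[, 1], median = q[, 2],
             upper = q[, 3], row.names = NULL)
}
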