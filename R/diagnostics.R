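## MCMC convergence diagnostics: potential scale reduction and effective
## sample size, implemented directly so they can be unit-tested against
## closed-form cases and cross-checked against coda.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat for one parameter: with m chains of n draws,
#' within-chain variance `W` (mean of chain variances), between-chain
#' variance `B = n * var(chain means)`, the statistic is
#' `sqrt(((n - 1)/n * W + B/n) / W)`.  Values near 1 indicate convergence.
#'
#' @param chains A numeric matrix, iterations x chains (or a list of equal
#'   length numeric vectors).
#' @return The scalar R-hat.
#' @examples
#' gelman_rubin(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))  # sqrt(3/4)
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L) {
    stop_bcmeta("R-hat needs at least 2 chains", class = "bcmeta_arg_error")
  }
  if (n < 4L) {
    stop_bcmeta("R-hat needs at least 4 draws per chain",
                class = "bcmeta_arg_error")
  }
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat
#'
#' [gelman_rubin()] applied after splitting each chain into halves, which also
#' detects non-stationarity within chains.  This is the statistic used by the
#' convergence gate in [fit_mcmc()].
#'
#' @inheritParams gelman_rubin
#' @export
split_rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  half <- floor(n / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(n - half + 1):n, , drop = FALSE])
  gelman_rubin(split)
}

#' Effective sample size
#'
#' Autocorrelation-based bulk ESS for one parameter across chains, following
#' the combined-chain estimator: autocovariances are averaged over chains,
#' converted to correlations of the pooled process using the between-chain
#' variance, summed over Geyer's initial monotone positive sequence of paired
#' lags, and inverted as `ESS = m * n / (1 + 2 * sum(rho))`.
#'
#' A constant chain has no information about mixing; the function returns 0
#' with a `degenerate` attribute in that case.
#'
#' @param chains A numeric matrix, iterations x chains, or a single numeric
#'   vector (one chain).
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  if (n < 4L) {
    stop_bcmeta("ESS needs at least 4 draws", class = "bcmeta_arg_error")
  }
  chain_vars <- apply(chains, 2, stats::var)
  if (all(chain_vars == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  W <- mean(chain_vars)
  var_plus <- (n - 1) / n * W
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(chains))
  ## chain-averaged autocovariances via FFT-free acf (biased, as standard)
  max_lag <- n - 2L
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(chains[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(as.matrix(acov))
  rho <- c(1, 1 - (W - mean_acov[-1]) / var_plus)  # rho[1] is lag 0
  ## Geyer initial monotone positive sequence over paired lags
  npair <- floor(length(rho) / 2)
  pair <- rho[seq_len(npair) * 2 - 1] + rho[seq_len(npair) * 2]
  pos <- which(pair <= 0)
  cut <- if (length(pos) > 0L) pos[1] - 1L else npair
  tau <- if (cut > 0L) -1 + 2 * sum(cummin(pair[seq_len(cut)])) else 1
  ess <- m * n / max(tau, .Machine$double.eps)
  min(ess, m * n * 1.5)  # cap superefficient antithetic estimates modestly
}
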