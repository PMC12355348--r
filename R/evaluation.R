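## Model comparison and checking: pointwise likelihoods, Pareto-smoothed
## importance-sampling leave-one-out cross-validation (PSIS-LOO), posterior
## predictive checks and randomized-quantile (PIT) residuals.

#' Pointwise log-likelihood matrix
#'
#' Entry (s, i) is the log normal density of observation i's log-ratio mean
#' under draw s: `dnorm(theta_hat_i, mu_i^(s), sqrt(sigma_hat_i^2 +
#' sigma_resid_s^2), log = TRUE)`.  Rows sum to the per-draw
#' [log_likelihood()].
#'
#' @param fit A `bcmeta_fit`.
#' @return A draws x observations matrix.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "bcmeta_fit"))
  design <- fit$design
  pooled <- pooled_draws(fit)
  mu <- posterior_mu(fit, pooled)
  n <- nrow(design$X)
  sigma2 <- outer(pooled[, "sigma_resid"]^2, design$sigma_hat^2, "+")
  theta <- matrix(design$theta_hat, nrow = nrow(mu), ncol = n, byrow = TRUE)
  stats::dnorm(theta, mu, sqrt(sigma2), log = TRUE)
}

## Zhang & Stephens (2009) quantile-grid profile-likelihood fit of the
## generalized Pareto distribution to exceedances x > 0.  Returns shape k
## (heavy tail k > 0) and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L) {
    stop_bcmeta("generalized-Pareto fit needs at least 5 exceedances",
                class = "bcmeta_arg_error")
  }
  prior_b <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_b * xstar)
  prof <- vapply(theta, function(th) {
    k <- mean(log1p(-th * x))
    n * (log(-th / k) - k - 1)
  }, 0)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(prof - prof[j])), 0)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  list(k = k, sigma = -k / theta_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(k * (-log1p(-p))) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (elpd) of
#' leave-one-out cross-validation from posterior draws alone.  For each
#' observation the raw importance ratios (the reciprocal likelihoods) have
#' their largest 20% (at least 5) replaced by order statistics of a
#' generalized-Pareto distribution fitted to that tail, truncated at the raw
#' maximum; the smoothed weights give
#' `elpd_i = log( sum_s w_s lik_s / sum_s w_s )`.  The fitted Pareto shape
#' k is reported per observation; k > 0.7 flags an unreliable estimate.
#'
#' @param loglik A draws x observations matrix from [pointwise_loglik()].
#' @return An object of class `bcmeta_loo`: `elpd`, `elpd_se`, `pointwise`
#'   (per-observation elpd_i), `pareto_k`, `n_bad_k`.
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  n <- ncol(loglik)
  if (any(!is.finite(loglik))) {
    stop_bcmeta("log-likelihood matrix has non-finite entries",
                class = "bcmeta_arg_error")
  }
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -loglik[, i]
    lw <- lw - max(lw)
    M <- max(5L, floor(0.2 * S))
    ord <- order(lw)
    if (M >= S - 1L) {
      ## too few draws to isolate a tail: use raw weights
      pareto_k[i] <- -Inf
      pointwise[i] <- logsumexp(lw + loglik[, i]) - logsumexp(lw)
      next
    }
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    exceed <- exp(lw[tail_ids]) - exp(cutoff)
    if (stats::sd(exceed) < 1e-12) {
      pareto_k[i] <- -Inf  # degenerate, near-equal weights
    } else {
      gp <- gpd_fit(exceed)
      pareto_k[i] <- gp$k
      pj <- (seq_len(M) - 0.5) / M
      smoothed <- exp(cutoff) +
        vapply(pj, gpd_quantile, 0, k = gp$k, sigma = gp$sigma)
      lw[tail_ids[order(lw[tail_ids])]] <- log(pmin(smoothed, exp(max(lw))))
    }
    pointwise[i] <- logsumexp(lw + loglik[, i]) - logsumexp(lw)
  }
  structure(list(elpd = sum(pointwise),
                 elpd_se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise,
                 pareto_k = pareto_k,
                 n_bad_k = sum(pareto_k > 0.7)),
            class = "bcmeta_loo")
}

#' Compare two models by their LOO estimates
#'
#' Difference in elpd (first minus second) with the standard error of the
#' pointwise differences.  Both results must come from the same observations.
#'
#' @param full,null `bcmeta_loo` objects.
#' @return A list with `elpd_diff` and `diff_se`.
#' @export
compare_elpd <- function(full, null) {
  stopifnot(inherits(full, "bcmeta_loo"), inherits(null, "bcmeta_loo"))
  if (length(full$pointwise) != length(null$pointwise)) {
    stop_bcmeta("models were evaluated on different numbers of observations",
                class = "bcmeta_arg_error")
  }
  d <- full$pointwise - null$pointwise
  list(elpd_diff = sum(d),
       diff_se = sqrt(length(d) * stats::var(d)))
}

#' Posterior predictive replicates
#'
#' Draws `n_rep` replicated data sets from the posterior predictive
#' distribution `y_rep ~ Normal(mu^(s), sqrt(sigma_hat^2 + sigma_resid_s^2))`
#' using posterior draws sampled without preference, and summarizes each
#' replicate by mean, SD, min and max.
#'
#' @param fit A `bcmeta_fit`.
#' @param n_rep Number of replicated data sets (default 1000).
#' @param seed Integer seed.
#' @return A list: `y_rep` (n_rep x observations matrix), `summaries`
#'   (data.frame with mean/sd/min/max per replicate), `observed` (the same
#'   four statistics of the data), `p_values` (two-sided tail probability of
#'   each observed statistic among the replicates).
#' @export
posterior_predictive <- function(fit, n_rep = 1000L, seed) {
  stopifnot(inherits(fit, "bcmeta_fit"))
  if (missing(seed)) stop_bcmeta("seed is required", class = "bcmeta_arg_error")
  if (n_rep < 2L) {
    stop_bcmeta("n_rep must be at least 2", class = "bcmeta_arg_error")
  }
  design <- fit$design
  pooled <- pooled_draws(fit)
  mu <- posterior_mu(fit, pooled)
  S <- nrow(pooled)
  n <- nrow(design$X)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  idx <- if (n_rep <= S) sample.int(S, n_rep) else
    sample.int(S, n_rep, replace = TRUE)
  sds <- sqrt(outer(pooled[idx, "sigma_resid"]^2, design$sigma_hat^2, "+"))
  y_rep <- matrix(stats::rnorm(n_rep * n, mu[idx, ], sds), nrow = n_rep)
  summaries <- data.frame(mean = rowMeans(y_rep),
                          sd = apply(y_rep, 1, stats::sd),
                          min = apply(y_rep, 1, min),
                          max = apply(y_rep, 1, max))
  obs <- c(mean = mean(design$theta_hat), sd = stats::sd(design$theta_hat),
           min = min(design$theta_hat), max = max(design$theta_hat))
  pvals <- vapply(names(obs), function(stat) {
    p <- mean(summaries[[stat]] >= obs[[stat]])
    p
  }, 0)
  list(y_rep = y_rep, summaries = summaries, observed = obs,
       p_values = pvals)
}

#' Randomized-quantile (PIT) residuals
#'
#' Probability integral transform of each observation under its posterior
#' predictive distribution: the fraction of replicated values below the
#' observation, randomized uniformly across ties and across the `1/(S+1)`
#' discretization so that a correctly specified model yields approximately
#' Uniform(0, 1) residuals.  Under-dispersion piles mass at 0 and 1.
#'
#' @param fit A `bcmeta_fit`.
#' @param seed Integer seed.
#' @param n_rep Number of predictive replicates used (default 1000).
#' @return Numeric vector of PIT values in \[0, 1\], one per observation.
#' @export
pit_residuals <- function(fit, seed, n_rep = 1000L) {
  if (missing(seed)) stop_bcmeta("seed is required", class = "bcmeta_arg_error")
  ppc <- posterior_predictive(fit, n_rep = n_rep, seed = seed)
  y_rep <- ppc$y_rep
  S <- nrow(y_rep)
  if (S < 1L) {
    stop_bcmeta("no predictive replicates", class = "bcmeta_arg_error")
  }
  theta <- fit$design$theta_hat
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) + 1L)
  vapply(seq_along(theta), function(i) {
    less <- sum(y_rep[, i] < theta[i])
    equal <- sum(y_rep[, i] == theta[i])
    (less + stats::runif(1) * (equal + 1)) / (S + 1)
  }, 0)
}
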