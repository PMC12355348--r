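## The Bayesian hierarchical meta-regression with known within-estimate
## sampling SD.
##
## Observation model, for estimate i in group (study) kappa = g[i]:
##
##   theta_hat_i ~ Normal(mu_i, sqrt(sigma_hat_i^2 + sigma_resid^2))
##   mu_i        = x_i' beta + zeta_{g[i]} * sigma_between
##
## with non-centered study intercepts zeta_k ~ Normal(0, 1), coefficients
## beta_t ~ Normal(0, 1) (the intercept is part of beta), and positive
## truncated Normal(0.5, 0.1) priors on sigma_between and sigma_resid.
## log_likelihood / log_prior / log_posterior are plain R implementations used
## directly by brute-force tests; fit_mcmc samples the same posterior with
## JAGS and gates the result on convergence diagnostics.

#' Linear predictor for a parameter state
#'
#' @param state List with `beta` (length-T), `zeta` (length-K),
#'   `sigma_between`, `sigma_resid`.
#' @param design A `bcmeta_design`.
#' @return Numeric vector of per-observation means `mu`.
#' @export
linear_predictor <- function(state, design) {
  drop(design$X %*% state$beta) +
    state$zeta[design$group_index] * state$sigma_between
}

#' Log-likelihood of the meta-regression
#'
#' Sum over observations of the normal log-density of the observed log-ratio
#' mean given the linear predictor, with total SD
#' `sqrt(sigma_hat^2 + sigma_resid^2)` combining the known per-estimate
#' sampling SD with the residual SD.
#'
#' @inheritParams linear_predictor
#' @return A single finite number for valid states.
#' @export
log_likelihood <- function(state, design) {
  if (state$sigma_resid <= 0 || state$sigma_between <= 0) {
    stop_bcmeta("scale parameters must be positive",
                class = "bcmeta_arg_error")
  }
  mu <- linear_predictor(state, design)
  total_sd <- sqrt(design$sigma_hat^2 + state$sigma_resid^2)
  sum(stats::dnorm(design$theta_hat, mu, total_sd, log = TRUE))
}

## log-density of Normal(mean, sd) truncated to (0, Inf), normalizer included
dtnorm_pos_log <- function(x, mean, sd) {
  ifelse(x <= 0, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

#' Log-prior of the meta-regression
#'
#' Normal(0, `prior_coef_sd`) on every coefficient and every standardized
#' study effect; positive truncated Normal(`prior_scale_mean`,
#' `prior_scale_sd`) on both scale parameters, with the truncation normalizer
#' included.  States with a non-positive scale have log-prior `-Inf`.
#'
#' @inheritParams linear_predictor
#' @param spec A [model_spec()].
#' @export
log_prior <- function(state, spec = model_spec()) {
  if (state$sigma_between <= 0 || state$sigma_resid <= 0) return(-Inf)
  sum(stats::dnorm(state$beta, 0, spec$prior_coef_sd, log = TRUE)) +
    sum(stats::dnorm(state$zeta, 0, 1, log = TRUE)) +
    dtnorm_pos_log(state$sigma_between, spec$prior_scale_mean,
                   spec$prior_scale_sd) +
    dtnorm_pos_log(state$sigma_resid, spec$prior_scale_mean,
                   spec$prior_scale_sd)
}

#' Unnormalized log-posterior
#'
#' `log_likelihood(state, design) + log_prior(state, spec)`; the target both
#' of the MCMC sampler and of the brute-force grid-integration tests.
#'
#' @inheritParams log_prior
#' @inheritParams linear_predictor
#' @export
log_posterior <- function(state, design, spec = model_spec()) {
  lp <- log_prior(state, spec)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(state, design)
}

jags_model_string <- function() {
  "model {
    for (i in 1:n) {
      mu[i] <- inprod(X[i, ], beta) + zeta[g[i]] * sigma_between
      theta_hat[i] ~ dnorm(mu[i], 1 / (sigma_hat[i]^2 + sigma_resid^2))
    }
    for (t in 1:T) { beta[t] ~ dnorm(0, 1 / coef_sd^2) }
    for (k in 1:K) { zeta[k] ~ dnorm(0, 1) }
    sigma_between ~ dnorm(scale_mean, 1 / scale_sd^2) T(0, )
    sigma_resid   ~ dnorm(scale_mean, 1 / scale_sd^2) T(0, )
  }"
}

#' Fit the meta-regression by MCMC
#'
#' Samples the posterior of the hierarchical meta-regression with JAGS
#' (Gibbs/slice sampling), using the spec's chain settings: by default 4
#' parallel chains of 10000 iterations with the first 5000 discarded as
#' warmup, i.e. 20000 posterior draws.  Chains are seeded deterministically
#' from `seed`, so a repeated call reproduces the draws exactly.
#'
#' The returned draws carry split R-hat and bulk effective-sample-size
#' diagnostics per parameter.  If `check_convergence` is `TRUE` (default),
#' the fit errors when any monitored parameter has split R-hat above 1.01 or
#' bulk ESS below 400, attaching the offending summaries.
#'
#' @param design A `bcmeta_design` from [build_design()].
#' @param spec A [model_spec()].
#' @param seed Integer seed for chain initialization and sampling.
#' @param check_convergence Gate the result on diagnostics (default `TRUE`).
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `bcmeta_fit`: `draws` (array iterations x
#'   chains x parameters), `parameters`, `diagnostics` (data.frame with
#'   `rhat`, `ess_bulk`), `design`, `spec`, `seed`.
#' @examples
#' \donttest{
#' sim <- generate_compilation(seed = 1)
#' adj <- batch_logratios(harmonize(sim$records), n_draws = 1e4,
#'                        master_seed = 1)
#' spec <- model_spec(chains = 2, iterations = 2000, warmup = 1000)
#' fit <- fit_mcmc(build_design(adj, spec), spec, seed = 1)
#' posterior_summary(fit, "sigma_between")
#' }
#' @export
fit_mcmc <- function(design, spec = model_spec(), seed,
                     check_convergence = TRUE, quiet = TRUE) {
  stopifnot(inherits(design, "bcmeta_design"))
  if (missing(seed)) stop_bcmeta("seed is required", class = "bcmeta_arg_error")
  K <- length(design$group_levels)
  if (K < 2L) {
    stop_bcmeta("need at least 2 groups", class = "bcmeta_arg_error")
  }
  data <- list(n = nrow(design$X), T = ncol(design$X), K = K,
               X = design$X, g = design$group_index,
               theta_hat = design$theta_hat, sigma_hat = design$sigma_hat,
               coef_sd = spec$prior_coef_sd,
               scale_mean = spec$prior_scale_mean,
               scale_sd = spec$prior_scale_sd)
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 1000 + ch) %% 2147483647))
  })
  n_adapt <- min(1000L, spec$warmup)
  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_string()), data = data,
                            inits = inits, n.chains = spec$chains,
                            n.adapt = n_adapt, quiet = quiet)
    if (spec$warmup > n_adapt) {
      stats::update(jm, n.iter = spec$warmup - n_adapt,
                    progress.bar = "none")
    }
    rjags::coda.samples(jm, variable.names = c("beta", "zeta",
                                               "sigma_between",
                                               "sigma_resid"),
                        n.iter = spec$iterations - spec$warmup,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  pnames <- colnames(samples[[1]])
  ## human-readable names: beta[t] -> design column, zeta[k] -> group level
  ## (JAGS drops the bracket index for length-1 vectors)
  nice <- pnames
  bt <- grepl("^beta(\\[\\d+\\])?$", pnames)
  bidx <- ifelse(pnames[bt] == "beta", 1L,
                 as.integer(sub("^beta\\[(\\d+)\\]$", "\\1", pnames[bt])))
  nice[bt] <- paste0("b_", design$column_names[bidx])
  nice[pnames == "zeta"] <- "zeta[1]"
  draws <- array(NA_real_,
                 dim = c(nrow(samples[[1]]), length(samples), length(pnames)),
                 dimnames = list(NULL, NULL, nice))
  for (ch in seq_along(samples)) draws[, ch, ] <- as.matrix(samples[[ch]])
  diagnostics <- data.frame(
    parameter = nice,
    rhat = vapply(seq_along(nice),
                  function(j) split_rhat(draws[, , j, drop = FALSE][, , 1]),
                  0),
    ess_bulk = vapply(seq_along(nice),
                      function(j)
                        effective_sample_size(draws[, , j, drop = FALSE][, , 1]),
                      0),
    row.names = NULL)
  fit <- structure(list(draws = draws, parameters = nice,
                        diagnostics = diagnostics, design = design,
                        spec = spec, seed = as.integer(seed)),
                   class = "bcmeta_fit")
  if (check_convergence) {
    bad <- diagnostics[is.finite(diagnostics$rhat) &
                         (diagnostics$rhat > 1.01 |
                            diagnostics$ess_bulk < 400), ]
    if (nrow(bad) > 0L) {
      msg <- paste0("MCMC convergence check failed for: ",
                    paste(sprintf("%s (rhat %.3f, ess %.0f)", bad$parameter,
                                  bad$rhat, bad$ess_bulk), collapse = "; "))
      cond <- structure(class = c("bcmeta_convergence_error", "bcmeta_error",
                                  "error", "condition"),
                        list(message = msg, call = sys.call(-1),
                             diagnostics = bad, fit = fit))
      stop(cond)
    }
  }
  fit
}

#' Extract a parameter's draws as an iterations x chains matrix
#'
#' @param fit A `bcmeta_fit`.
#' @param parameter Parameter name (see `fit$parameters`).
#' @export
parameter_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "bcmeta_fit"))
  if (!parameter %in% fit$parameters) {
    stop_bcmeta("unknown parameter '", parameter, "'",
                class = "bcmeta_arg_error")
  }
  fit$draws[, , parameter]
}

## all post-warmup draws pooled across chains, as draws x parameters matrix
pooled_draws <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Posterior summary of one parameter
#'
#' Median and central 95% interval over pooled post-warmup draws, with the
#' convergence diagnostics for that parameter.
#'
#' @inheritParams parameter_draws
#' @return A one-row data.frame: `parameter`, `median`, `q2.5`, `q97.5`,
#'   `rhat`, `ess_bulk`.
#' @export
posterior_summary <- function(fit, parameter = NULL) {
  stopifnot(inherits(fit, "bcmeta_fit"))
  pars <- parameter %||% fit$parameters
  pooled <- pooled_draws(fit)
  out <- do.call(rbind, lapply(pars, function(p) {
    q <- stats::quantile(pooled[, p], c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = p, median = q[2], q2.5 = q[1], q97.5 = q[3])
  }))
  merge(out, fit$diagnostics, by = "parameter", sort = FALSE)
}

#' Fold-variation implied by between-study heterogeneity
#'
#' Transforms draws of the between-study SD `sigma` into draws of
#' `exp(2 * sigma)`, the average multiplicative spread in the
#' autochthonous:allochthonous ratio attributable to study identity after
#' accounting for fixed effects.  A between-study SD of 0.65 implies about a
#' 3.7-fold variation.
#'
#' @param sigma_between_draws Numeric vector (or matrix) of posterior draws.
#' @return A list with `draws` (`exp(2 * sigma)`), `median`, `q2.5`, `q97.5`.
#' @examples
#' fold_variation(0.65)$median  # about 3.67
#' @export
fold_variation <- function(sigma_between_draws) {
  x <- exp(2 * as.numeric(sigma_between_draws))
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  list(draws = x, median = q[2], q2.5 = q[1], q97.5 = q[3])
}

#' Bayesian R-squared
#'
#' For each posterior draw `s`, `R2_s = V_fit / (V_fit + V_res)` where
#' `V_fit` is the variance across observations of the linear predictor
#' (including the study intercepts) and `V_res` is the mean modeled residual
#' variance `sigma_hat_i^2 + sigma_resid_s^2`.
#'
#' @param fit A `bcmeta_fit`.
#' @return A list with per-draw `draws` (all in \[0, 1\]), `median`, `q2.5`,
#'   `q97.5`.
#' @export
bayes_r2 <- function(fit) {
  stopifnot(inherits(fit, "bcmeta_fit"))
  design <- fit$design
  if (nrow(design$X) < 2L) {
    stop_bcmeta("Bayesian R-squared needs at least 2 observations",
                class = "bcmeta_arg_error")
  }
  pooled <- pooled_draws(fit)
  mu <- posterior_mu(fit, pooled)
  v_fit <- apply(mu, 1, stats::var)
  v_res <- vapply(pooled[, "sigma_resid"],
                  function(s) mean(design$sigma_hat^2 + s^2), 0)
  r2 <- v_fit / (v_fit + v_res)
  q <- stats::quantile(r2, c(0.025, 0.5, 0.975), names = FALSE)
  list(draws = r2, median = q[2], q2.5 = q[1], q97.5 = q[3])
}

## draws x observations matrix of linear predictors
posterior_mu <- function(fit, pooled = pooled_draws(fit)) {
  design <- fit$design
  beta_cols <- paste0("b_", design$column_names)
  zeta_cols <- grep("^zeta\\[", colnames(pooled), value = TRUE)
  zeta_idx <- as.integer(sub("^zeta\\[(\\d+)\\]$", "\\1", zeta_cols))
  beta <- pooled[, beta_cols, drop = FALSE]
  zeta <- pooled[, zeta_cols, drop = FALSE][, order(zeta_idx), drop = FALSE]
  fixed <- beta %*% t(design$X)
  fixed + zeta[, design$group_index, drop = FALSE] * pooled[, "sigma_between"]
}
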