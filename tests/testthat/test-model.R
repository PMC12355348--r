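# A one-column design with fully specified data, for density-level oracles.
make_density_design <- function(theta_hat, sigma_hat, groups = NULL) {
  n <- length(theta_hat)
  groups <- groups %||% rep(1L, n)
  structure(list(X = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
                 column_names = "intercept",
                 centers = c(intercept = 0), scales = c(intercept = 1),
                 group_index = groups, group_levels = unique(groups),
                 theta_hat = theta_hat, sigma_hat = sigma_hat,
                 estimate_id = sprintf("obs%d", seq_len(n))),
            class = "bcmeta_design")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("log-likelihood matches the normal-density oracle", {
  st <- list(beta = 1, zeta = 0, sigma_between = 0.5, sigma_resid = 1)
  d <- make_density_design(theta_hat = 1, sigma_hat = 1)
  expect_equal(log_likelihood(st, d), dnorm(1, 1, sqrt(2), log = TRUE))
  expect_equal(log_likelihood(st, d), -1.2655, tolerance = 1e-4)

  ## zero sampling SD, matching mean: standard normal at its mode
  d0 <- make_density_design(theta_hat = 1, sigma_hat = 0)
  expect_equal(log_likelihood(st, d0), -0.5 * log(2 * pi), tolerance = 1e-12)

  ## additivity over identical observations
  d2 <- make_density_design(theta_hat = c(1, 1), sigma_hat = c(1, 1))
  expect_equal(log_likelihood(st, d2), 2 * log_likelihood(st, d))
  expect_error(log_likelihood(list(beta = 1, zeta = 0, sigma_between = 0.5,
                                   sigma_resid = -1), d),
               class = "bcmeta_arg_error")
})

test_that("log-prior matches closed-form truncated-normal densities", {
  spec <- model_spec()
  st <- list(beta = 0, zeta = c(0, 0), sigma_between = 0.5, sigma_resid = 0.5)
  scale_mode <- dnorm(0.5, 0.5, 0.1, log = TRUE) -
    pnorm(0, 0.5, 0.1, lower.tail = FALSE, log.p = TRUE)
  expect_equal(log_prior(st, spec),
               3 * dnorm(0, log = TRUE) + 2 * scale_mode)
  ## lengthening zeta adds exactly the corresponding standard-normal terms
  st4 <- st
  st4$zeta <- c(st$zeta, 0.7, -0.2)
  expect_equal(log_prior(st4, spec),
               log_prior(st, spec) + dnorm(0.7, log = TRUE) +
                 dnorm(-0.2, log = TRUE))
  st_bad <- st
  st_bad$sigma_resid <- -0.1
  expect_identical(log_prior(st_bad, spec), -Inf)
})

test_that("log-posterior is likelihood plus prior and exchangeable in studies", {
  spec <- model_spec()
  d <- make_density_design(theta_hat = c(0.4, -0.2, 0.9),
                           sigma_hat = c(0.3, 0.5, 0.4),
                           groups = c(1L, 2L, 2L))
  set.seed(42)
  for (i in 1:10) {
    st <- list(beta = rnorm(1), zeta = rnorm(2),
               sigma_between = runif(1, 0.2, 1),
               sigma_resid = runif(1, 0.2, 1))
    expect_equal(log_posterior(st, d, spec),
                 log_likelihood(st, d) + log_prior(st, spec))
  }
  ## relabeling studies (and permuting zeta accordingly) leaves it unchanged
  d_swap <- make_density_design(theta_hat = c(0.4, -0.2, 0.9),
                                sigma_hat = c(0.3, 0.5, 0.4),
                                groups = c(2L, 1L, 1L))
  st <- list(beta = 0.3, zeta = c(0.5, -1), sigma_between = 0.6,
             sigma_resid = 0.4)
  st_swap <- st
  st_swap$zeta <- st$zeta[c(2, 1)]
  expect_equal(log_posterior(st, d, spec),
               log_posterior(st_swap, d_swap, spec))
})

test_that("non-centered and centered parameterizations agree after the
           change of variables", {
  spec <- model_spec()
  set.seed(7)
  for (i in 1:10) {
    zeta <- rnorm(3)
    sb <- runif(1, 0.2, 1)
    b <- zeta * sb
    noncentered <- sum(dnorm(zeta, 0, 1, log = TRUE)) - 3 * log(sb)
    centered <- sum(dnorm(b, 0, sb, log = TRUE))
    expect_equal(noncentered, centered)
  }
})

test_that("MCMC matches brute-force grid integration on a small problem", {
  theta_hat <- c(0.8, 0.4, -0.3)
  sigma_hat <- c(0.3, 0.4, 0.5)
  groups <- c(1L, 1L, 2L)
  d <- make_density_design(theta_hat, sigma_hat, groups)
  spec <- model_spec(fixed_effects = character(0), chains = 4L,
                     iterations = 6000L, warmup = 2000L)

  ## independent grid quadrature over (b0, z1, z2, sb, sr)
  b0 <- seq(-2, 2, length.out = 41)
  zz <- seq(-3.5, 3.5, length.out = 31)
  sb <- seq(0.15, 0.95, length.out = 17)
  sr <- seq(0.15, 0.95, length.out = 17)
  lp_b0 <- dnorm(b0, log = TRUE)
  lp_z <- dnorm(zz, log = TRUE)
  wsum <- 0; mu1_sum <- 0
  for (si in sb) for (ri in sr) {
    lp_scales <- dnorm(si, 0.5, 0.1, log = TRUE) +
      dnorm(ri, 0.5, 0.1, log = TRUE)
    sd1 <- sqrt(sigma_hat[1:2]^2 + ri^2)
    sd2 <- sqrt(sigma_hat[3]^2 + ri^2)
    ## study 1 terms depend on (b0, z1); study 2 on (b0, z2)
    A <- outer(b0, zz, function(b, z)
      dnorm(theta_hat[1], b + z * si, sd1[1], log = TRUE) +
        dnorm(theta_hat[2], b + z * si, sd1[2], log = TRUE))
    B <- outer(b0, zz, function(b, z)
      dnorm(theta_hat[3], b + z * si, sd2, log = TRUE))
    wA <- exp(A + lp_b0 + rep(lp_z, each = length(b0)))
    wB <- exp(B + rep(lp_z, each = length(b0)))
    ## joint weight factorizes given b0: sum z2 out of B, z1 out of A
    gB <- rowSums(wB)                      # over z2, by b0
    w_b0z1 <- wA * gB                      # joint in (b0, z1)
    w <- sum(w_b0z1) * exp(lp_scales)
    mu1 <- outer(b0, zz * si, "+")         # b0 + z1 * sb
    wsum <- wsum + w
    mu1_sum <- mu1_sum + sum(w_b0z1 * mu1) * exp(lp_scales)
  }
  grid_mean_mu1 <- mu1_sum / wsum

  fit <- suppressWarnings(fit_mcmc(d, spec, seed = 2,
                                   check_convergence = FALSE))
  pooled <- fit$draws
  mu1_draws <- pooled[, , "b_intercept"] +
    pooled[, , "zeta[1]"] * pooled[, , "sigma_between"]
  expect_lt(abs(mean(mu1_draws) - grid_mean_mu1), 0.02)
})

test_that("seeded fits are reproducible and gated on convergence", {
  fx <- small_adjusted()
  spec <- test_spec(iterations = 800L, warmup = 400L)
  d <- build_design(fx$adjusted, spec)
  f1 <- suppressWarnings(fit_mcmc(d, spec, seed = 3,
                                  check_convergence = FALSE))
  f2 <- suppressWarnings(fit_mcmc(d, spec, seed = 3,
                                  check_convergence = FALSE))
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws)[1] * dim(f1$draws)[2],
               spec$chains * (spec$iterations - spec$warmup))
  expect_true(all(f1$draws[, , "sigma_between"] > 0))
  ## far-too-short chains cannot reach the ESS gate
  tiny <- test_spec(iterations = 60L, warmup = 30L)
  expect_error(suppressWarnings(fit_mcmc(build_design(fx$adjusted, tiny),
                                         tiny, seed = 3)),
               class = "bcmeta_convergence_error")
})

test_that("Gelman-Rubin matches hand computations", {
  expect_equal(gelman_rubin(cbind(1:4, 1:4)), sqrt(3 / 4))
  set.seed(1)
  long <- cbind(rnorm(20000), rnorm(20000))
  expect_gt(gelman_rubin(long), 0.99)
  expect_lt(gelman_rubin(long), 1.01)
  shifted <- cbind(rnorm(1000), rnorm(1000) + 10)
  expect_gt(gelman_rubin(shifted), 1.5)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)),
               class = "bcmeta_arg_error")
  ## cross-check against coda on a realistic pair of chains
  set.seed(2)
  ch <- cbind(arima.sim(list(ar = 0.5), 5000), arima.sim(list(ar = 0.5), 5000))
  coda_psrf <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(ch[, 1]),
                                                 coda::mcmc(ch[, 2])),
                                 autoburnin = FALSE)$psrf[1]
  expect_equal(gelman_rubin(ch), coda_psrf, tolerance = 0.01)
})

test_that("effective sample size tracks independence and autocorrelation", {
  set.seed(5)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_equal(effective_sample_size(iid), 4000, tolerance = 0.15)
  rho <- 0.9
  ar <- sapply(1:4, function(i) as.numeric(arima.sim(list(ar = rho), 5000)))
  S <- 4 * 5000
  expect_equal(effective_sample_size(ar), S * (1 - rho) / (1 + rho),
               tolerance = 0.25)
  flat <- matrix(1, 100, 2)
  expect_equal(as.numeric(effective_sample_size(flat)), 0)
  expect_true(isTRUE(attr(effective_sample_size(flat), "degenerate")))
})

test_that("fold-variation transforms between-study SD as exp(2 sigma)", {
  expect_equal(fold_variation(0.65)$median, exp(1.3))
  expect_equal(round(fold_variation(0.65)$median, 1), 3.7)
  expect_equal(fold_variation(0)$median, 1)
  expect_equal(fold_variation(log(2) / 2)$median, 2)
})

test_that("Bayesian R-squared matches its variance-decomposition formula", {
  X <- cbind(intercept = 1, x = c(-1, 0, 1))
  st <- list(beta = c(1, 1), zeta = c(0, 0), sigma_between = 0.5,
             sigma_resid = 1)
  fit <- fake_fit(list(st), X, group_index = c(1L, 1L, 2L),
                  sigma_hat = c(1, 1, 1), theta_hat = c(0, 1, 2))
  ## mu = (0, 1, 2): V_fit = 1, V_res = mean(1 + 1) = 2
  expect_equal(bayes_r2(fit)$median, 1 / 3)

  noiseless <- st; noiseless$sigma_resid <- 1e-9
  fitn <- fake_fit(list(noiseless), X, c(1L, 1L, 2L),
                   sigma_hat = c(0, 0, 0), theta_hat = c(0, 1, 2))
  expect_equal(bayes_r2(fitn)$median, 1, tolerance = 1e-12)

  flat <- st; flat$beta <- c(1, 0)
  fitf <- fake_fit(list(flat), X, c(1L, 1L, 2L), sigma_hat = c(1, 1, 1),
                   theta_hat = c(0, 1, 2))
  expect_equal(bayes_r2(fitf)$median, 0)

  st1 <- st; st1$zeta <- 0
  one <- fake_fit(list(st1), X[1, , drop = FALSE], 1L, 1, 0)
  expect_error(bayes_r2(one), class = "bcmeta_arg_error")
})
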