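test_that("pointwise log-likelihood rows sum to the joint log-likelihood", {
  X <- cbind(intercept = 1, x = c(-1, 0, 1))
  s1 <- list(beta = c(0.5, 0.3), zeta = c(0.2, -0.4), sigma_between = 0.6,
             sigma_resid = 0.5)
  s2 <- list(beta = c(-0.1, 0.8), zeta = c(-1, 0.3), sigma_between = 0.4,
             sigma_resid = 0.7)
  fit <- fake_fit(list(s1, s2, s1), X, group_index = c(1L, 2L, 2L),
                  sigma_hat = c(0.3, 0.5, 0.2),
                  theta_hat = c(0.1, -0.6, 0.9))
  ll <- pointwise_loglik(fit)
  expect_equal(dim(ll), c(3L, 3L))
  d <- fit$design
  expect_equal(rowSums(ll),
               c(log_likelihood(s1, d), log_likelihood(s2, d),
                 log_likelihood(s1, d)))
  ## identical draws give identical rows
  expect_equal(ll[1, ], ll[3, ])
  ## hand case: one observation at its mean with unit scales
  st <- list(beta = c(1, 0), zeta = c(0, 0), sigma_between = 0.5,
             sigma_resid = 1)
  f1 <- fake_fit(list(st), X, c(1L, 1L, 2L), sigma_hat = c(1, 1, 1),
                 theta_hat = c(1, 1, 1))
  expect_equal(pointwise_loglik(f1)[1, 1], dnorm(1, 1, sqrt(2), log = TRUE))
})

test_that("PSIS-LOO is exact for degenerate weights", {
  ## constant log-likelihood across draws: weights cancel exactly
  ll <- matrix(rep(c(-1.3, -0.7, -2.1), each = 50), nrow = 50)
  res <- psis_loo(ll)
  expect_equal(res$pointwise, c(-1.3, -0.7, -2.1))
  expect_equal(res$elpd, sum(c(-1.3, -0.7, -2.1)))
  ## one observation, two equal likelihoods 0.5
  res2 <- psis_loo(matrix(log(0.5), nrow = 2, ncol = 1))
  expect_equal(res2$elpd, log(0.5))
})

test_that("PSIS-LOO matches exact refit LOO on a conjugate toy", {
  ## y_i ~ N(mu, 1), mu ~ N(0, 1): every leave-one-out posterior is closed
  ## form, so exact LOO is available by refitting analytically
  set.seed(31)
  n <- 5
  y <- rnorm(n, 0.8, 1)
  S <- 4000
  post_mean <- sum(y) / (n + 1)
  post_sd <- sqrt(1 / (n + 1))
  mu_draws <- rnorm(S, post_mean, post_sd)
  ll <- sapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE))
  res <- psis_loo(ll)
  exact <- sum(vapply(seq_len(n), function(i) {
    m_i <- sum(y[-i]) / n          # posterior without observation i
    dnorm(y[i], m_i, sqrt(1 + 1 / n), log = TRUE)
  }, 0))
  expect_lt(abs(res$elpd - exact), 0.1)
  ## LOO never beats the in-sample log pointwise predictive density
  lpd <- sum(log(colMeans(exp(ll))))
  expect_lte(res$elpd, lpd)
  expect_true(all(is.finite(res$pareto_k) | res$pareto_k == -Inf))
})

test_that("model comparison is antisymmetric and zero on self", {
  set.seed(8)
  ll_a <- matrix(rnorm(600, -1), 100, 6)
  ll_b <- matrix(rnorm(600, -1.5), 100, 6)
  a <- psis_loo(ll_a)
  b <- psis_loo(ll_b)
  self <- compare_elpd(a, a)
  expect_identical(self$elpd_diff, 0)
  expect_identical(self$diff_se, 0)
  ab <- compare_elpd(a, b)
  ba <- compare_elpd(b, a)
  expect_equal(ab$elpd_diff, -ba$elpd_diff)
  expect_equal(ab$diff_se, ba$diff_se)
  short <- psis_loo(ll_b[, 1:3])
  expect_error(compare_elpd(a, short), class = "bcmeta_arg_error")
})

test_that("LOO prefers the true model when the signal is strong", {
  ## strong habitat-like effect: full model beats intercept-only clearly
  set.seed(91)
  wins <- 0L
  for (r in 1:5) {
    n <- 40
    x <- rep(c(0, 1), each = n / 2)
    mu <- 2.5 * x
    sigma_hat <- rep(0.4, n)
    y <- rnorm(n, mu, 0.5)
    S <- 600
    ## draws from approximate posteriors of each model
    beta_full <- cbind(rnorm(S, 0, 0.1), rnorm(S, 2.5, 0.1))
    ll_full <- sapply(seq_len(n), function(i)
      dnorm(y[i], beta_full[, 1] + beta_full[, 2] * x[i],
            sqrt(sigma_hat[i]^2 + 0.25), log = TRUE))
    b0 <- rnorm(S, mean(y), 0.15)
    ll_null <- sapply(seq_len(n), function(i)
      dnorm(y[i], b0, sqrt(sigma_hat[i]^2 + 0.25), log = TRUE))
    cmp <- compare_elpd(psis_loo(ll_full), psis_loo(ll_null))
    if (cmp$elpd_diff > 2 * cmp$diff_se) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("posterior predictive replicates are seeded and degenerate-exact", {
  X <- cbind(intercept = 1, x = c(-1, 0, 1))
  st <- list(beta = c(1, 1), zeta = c(0, 0), sigma_between = 0.5,
             sigma_resid = 0)
  fit <- fake_fit(list(st, st), X, c(1L, 1L, 2L), sigma_hat = c(0, 0, 0),
                  theta_hat = c(0, 1, 2))
  p1 <- posterior_predictive(fit, n_rep = 10, seed = 4)
  p2 <- posterior_predictive(fit, n_rep = 10, seed = 4)
  expect_identical(p1$y_rep, p2$y_rep)
  ## zero sampling and residual SD: replicates equal mu exactly
  expect_true(all(abs(sweep(p1$y_rep, 2, c(0, 1, 2))) < 1e-12))
  expect_error(posterior_predictive(fit, n_rep = 1, seed = 1),
               class = "bcmeta_arg_error")
})

test_that("PIT residuals live in [0, 1] and are seeded", {
  fx <- small_adjusted(seed = 55)
  spec <- test_spec(iterations = 600L, warmup = 300L)
  fit <- suppressWarnings(fit_mcmc(build_design(fx$adjusted, spec), spec,
                                   seed = 5, check_convergence = FALSE))
  pit <- pit_residuals(fit, seed = 6, n_rep = 400)
  expect_length(pit, nrow(fx$adjusted))
  expect_true(all(pit >= 0 & pit <= 1))
  expect_identical(pit, pit_residuals(fit, seed = 6, n_rep = 400))
})
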