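test_that("pooled source statistics are unweighted and permutation-invariant", {
  one <- pooled_source_stats(40)
  expect_equal(one$mean, 40)
  expect_equal(one$n_datasets, 1L)
  two <- pooled_source_stats(c(20, 30))
  expect_equal(two$mean, 25)
  set.seed(2)
  x <- runif(9, 0, 100)
  expect_equal(pooled_source_stats(x)$mean,
               pooled_source_stats(sample(x))$mean)
  expect_error(pooled_source_stats(numeric(0)), class = "bcmeta_arg_error")
})

test_that("bootstrap density degenerates to a point mass when SD is zero", {
  d <- bootstrap_density(data.frame(mean_pct = 40, sd_pct = 0), seed = 1)
  expect_true(d$point_mass)
  expect_true(all(d$quantiles == 40))
  expect_equal(d$n_draws, 1000L)
})

test_that("bootstrap density is seeded, normalized and monotone in quantiles", {
  contrib <- data.frame(mean_pct = c(25, 60), sd_pct = c(8, 12))
  d1 <- bootstrap_density(contrib, n_boot = 2000, seed = 9)
  d2 <- bootstrap_density(contrib, n_boot = 2000, seed = 9)
  expect_identical(d1$density, d2$density)
  expect_true(all(d1$density >= 0))
  ## trapezoid mass on the grid integrates to ~1
  mass <- sum(diff(d1$grid) * (head(d1$density, -1) + tail(d1$density, -1)) / 2)
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_true(all(diff(d1$quantiles) >= 0))
})

test_that("pooled bootstrap quantiles match the truncated-normal mixture", {
  contrib <- data.frame(mean_pct = c(30, 70), sd_pct = c(5, 5))
  d <- bootstrap_density(contrib, n_boot = 1e5, seed = 21)
  ptrunc <- function(q, m, s) {
    (pnorm(q, m, s) - pnorm(0, m, s)) /
      (pnorm(100, m, s) - pnorm(0, m, s))
  }
  mix_cdf <- function(q) 0.5 * ptrunc(q, 30, 5) + 0.5 * ptrunc(q, 70, 5)
  for (j in seq_along(d$quantiles)) {
    p <- c(0.025, 0.25, 0.5, 0.75, 0.975)[j]
    exact <- uniroot(function(q) mix_cdf(q) - p, c(0, 100),
                     tol = 1e-8)$root
    expect_lt(abs(d$quantiles[[j]] - exact), 1)   # within 1 percentage point
  }
})

test_that("two-source mixing recovers endpoint and midpoint identities", {
  s1 <- iso_signature(-30, 1, 5)
  s2 <- iso_signature(-20, 1, 5)
  expect_equal(two_source_mixing(s1, s1, s2)$f1, 1)
  expect_equal(two_source_mixing(iso_signature(-25, 1, 5), s1, s2)$f1, 0.5)
  ## swapping sources flips the fraction, SE unchanged
  a <- two_source_mixing(iso_signature(-23, 1.5, 4), s1, s2)
  b <- two_source_mixing(iso_signature(-23, 1.5, 4), s2, s1)
  expect_equal(a$f1, 1 - b$f1)
  expect_equal(a$se_f1, b$se_f1)
  ## out-of-interval mixtures are flagged, not truncated
  out <- two_source_mixing(iso_signature(-32, 1, 5), s1, s2)
  expect_true(out$extrapolated)
  expect_gt(out$f1, 1)
  expect_error(two_source_mixing(s1, s2, s2),
               class = "bcmeta_indeterminate_error")
})

test_that("delta-method SE matches Monte-Carlo error propagation", {
  ## documented case: 10 per-mil separation, f1 = 0.5, all signature SEs 1
  mix <- iso_signature(-25, 1, 1)
  s1 <- iso_signature(-30, 1, 1)
  s2 <- iso_signature(-20, 1, 1)
  res <- two_source_mixing(mix, s1, s2)
  expect_equal(res$f1, 0.5)
  expect_equal(res$se_f1, sqrt(0.015), tolerance = 1e-12)
  set.seed(17)
  n <- 1e6
  d2 <- rnorm(n, -20, 1)   # the same source-2 draw enters both terms
  f_draws <- (rnorm(n, -25, 1) - d2) / (rnorm(n, -30, 1) - d2)
  ## the denominator crosses zero with positive density, so the ratio has no
  ## finite variance; the Monte-Carlo scale is the central 68.27% half-width
  mc_se <- diff(quantile(f_draws, c(0.15865, 0.84135))) / 2
  expect_equal(res$se_f1, unname(mc_se), tolerance = 0.02)
})

test_that("habitat-by-source densities pool the correct rows", {
  records <- tiny_compilation()
  contrib <- data.frame(
    estimate_id = c("e1", "e1", "e2", "e4"),
    source_name = c("mangrove", "spom", "macroalgae", "macroalgae"),
    mean_pct = c(60, 40, 20, 30),
    sd_pct = c(5, 5, 4, 6),
    n_estimates = c(3L, 3L, 2L, 2L))
  dens <- habitat_source_densities(contrib, records, n_boot = 500, seed = 3)
  summ <- attr(dens, "summary")
  sea_macro <- summ[summ$habitat == "seagrass" &
                      summ$source_name == "macroalgae", ]
  expect_equal(sea_macro$mean, 25)     # e2 and e4 are both seagrass
  expect_equal(sea_macro$n_datasets, 2L)
  expect_s3_class(dens[["seagrass.macroalgae"]], "bcmeta_density")
})
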