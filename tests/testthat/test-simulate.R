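test_that("generation is deterministic given the seed", {
  a <- generate_compilation(seed = 99)
  b <- generate_compilation(seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$zeta, b$truth$zeta)
  expect_false(identical(generate_compilation(seed = 100)$records,
                         a$records))
})

test_that("default compilation reproduces the documented data structure", {
  sim <- generate_compilation(seed = 7)
  rec <- sim$records
  expect_equal(nrow(rec), 110L)
  expect_equal(length(unique(rec$study_id)), 78L)
  ## unbalanced climate: tropical fraction among mangrove records should sit
  ## inside the 95% binomial interval around 0.83
  mang <- rec[rec$habitat == "mangrove", ]
  phat <- mean(mang$climate == "tropical")
  half <- 1.96 * sqrt(0.83 * 0.17 / nrow(mang))
  expect_lt(abs(phat - 0.83), half + 1e-12)
  ## saltmarsh is never tropical under the default config
  expect_true(all(rec$climate[rec$habitat == "saltmarsh"] == "temperate"))
  expect_true(all(rec$n_replicates >= 2 & rec$n_replicates <= 35))
  expect_true(all(rec$depth_mid_m >= 0))
  expect_true(all(rec$var_kind %in% c("sd", "se", "ci95", "variance")))
})

test_that("generated marginals match the configured moments at scale", {
  big <- generate_compilation(
    generator_config(n_studies = 400L, n_estimates = 1200L,
                     n_multi_studies = 300L), seed = 3)
  rec <- big$records
  n <- nrow(rec)
  expect_lt(abs(mean(rec$depth_mid_m) - 0.20), 3 * 0.27 / sqrt(n))
  expect_lt(abs(sd(rec$depth_mid_m) - 0.27), 0.05)
  expect_true(abs(median(rec$n_replicates) - 6) <= 1)
  expect_lt(abs(mean(rec$habitat == "seagrass") - 56 / 110),
            3 * sqrt(0.51 * 0.49 / n))
})

test_that("degenerate truth collapses all true log-ratios to the intercept", {
  zero_beta <- c(intercept = -0.2, habitat_saltmarsh = 0,
                 habitat_seagrass = 0, climate_temperate = 0,
                 method_standard = 0, method_other = 0, depth_mid_m = 0,
                 n_endmembers = 0, n_replicates = 0)
  sim <- generate_compilation(
    generator_config(true_beta = zero_beta, sigma_between = 1e-12,
                     sigma_resid = 1e-12), seed = 5)
  expect_true(all(abs(sim$truth$theta_true - (-0.2)) < 1e-9))
})

test_that("back-transform round-trips through the Monte-Carlo engine", {
  ## delta-method validity: small sampling SDs reproduce (theta_hat,
  ## sigma_hat) within 5% relative error
  cfg <- generator_config(sigma_hat_meanlog = log(0.22),
                          sigma_hat_sdlog = 0.3)
  sim <- generate_compilation(cfg, seed = 13)
  keep <- sim$truth$sigma_hat <= 0.3
  expect_gt(sum(keep), 20)
  adj <- batch_logratios(harmonize(sim$records[keep, ]), n_draws = 5e4,
                         master_seed = 13)
  ratio <- adj$logratio_sd / sim$truth$sigma_hat[keep]
  expect_true(stats::quantile(abs(ratio - 1), 0.9) < 0.05)
  expect_lt(max(abs(adj$logratio_mean - sim$truth$theta_hat[keep])), 0.06)
})

test_that("source table is seeded and respects degenerate profiles", {
  t1 <- generate_source_table(seed = 4)
  expect_identical(t1, generate_source_table(seed = 4))
  expect_true(all(t1$mean_pct >= 0 & t1$mean_pct <= 100))
  expect_true(all(t1$sd_pct >= 0))
  ## single source configured at 100% yields constant rows
  solo <- generator_config(
    source_profiles = list(
      seagrass = data.frame(source_name = "seagrass", mean_pct = 100,
                            between_sd = 0, within_sd_mean = 5,
                            report_prob = 1)),
    n_datasets_per_habitat = c(seagrass = 10L))
  t2 <- generate_source_table(solo, seed = 4)
  expect_true(all(t2$mean_pct == 100))
})

test_that("pooled statistics recover the configured source means at scale", {
  cfg <- generator_config(n_datasets_per_habitat = c(saltmarsh = 20L,
                                                     mangrove = 34L,
                                                     seagrass = 370L))
  tab <- generate_source_table(cfg, seed = 6)
  sea_man <- tab[tab$habitat == "seagrass" & tab$source_name == "mangrove", ]
  expect_gt(nrow(sea_man), 150)   # ~ 370 * 30/56 reporting probability
  expect_lt(abs(pooled_source_stats(sea_man)$mean - 27), 2)
})

test_that("recovery experiment reports coverage per parameter", {
  cfg <- generator_config(n_studies = 12L, n_estimates = 18L,
                          n_multi_studies = 4L)
  spec <- model_spec(chains = 2L, iterations = 700L, warmup = 350L)
  rec <- suppressWarnings(
    recovery_experiment(cfg, n_replicates = 2L, seed = 19, spec = spec,
                        n_draws = 5e3))
  expect_equal(rec$n_failed, 0L)
  expect_true("sigma_between" %in% rec$per_parameter$parameter)
  expect_true(all(c("coverage", "median_bias", "n_covered") %in%
                    names(rec$per_parameter)))
  ## at least the intercept, the scales and the continuous effects appear in
  ## both replicates (rare categorical levels can drop at this tiny size)
  expect_gte(nrow(rec$per_parameter), 5L)
})
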