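# Shared fixtures, all built in code.

# A tiny hand-written compilation covering every variability kind.
tiny_compilation <- function() {
  data.frame(
    estimate_id = c("e1", "e2", "e3", "e4"),
    study_id = c("s1", "s1", "s2", "s3"),
    habitat = c("mangrove", "seagrass", "saltmarsh", "seagrass"),
    climate = c("tropical", "tropical", "temperate", "temperate"),
    method = c("bayesian", "standard", "other", "standard"),
    depth_mid_m = c(0.1, 0.3, 0.05, 0.6),
    n_endmembers = c(3L, 2L, 4L, 2L),
    n_replicates = c(9L, 4L, 6L, 5L),
    auto_mean_pct = c(60, 40, 55, 30),
    var_kind = c("sd", "se", "ci95", "variance"),
    var_a = c(12, 2, 45, 25),
    var_b = c(NA, NA, 65, NA),
    stringsAsFactors = FALSE)
}

# A synthetic fit-ready adjusted-estimate table (no MCMC involved).
small_adjusted <- function(seed = 101, n_studies = 20L, n_estimates = 30L,
                           n_draws = 5e3) {
  sim <- generate_compilation(
    generator_config(n_studies = n_studies, n_estimates = n_estimates,
                     n_multi_studies = min(8L, n_studies %/% 2L)),
    seed = seed)
  list(adjusted = batch_logratios(harmonize(sim$records), n_draws = n_draws,
                                  master_seed = seed),
       truth = sim$truth, records = sim$records)
}

# A hand-built fit object with fully known draws, for exact-value tests of
# everything downstream of MCMC (pointwise likelihoods, R2, PPC, PIT).
fake_fit <- function(draws_list, X, group_index, sigma_hat, theta_hat,
                     spec = model_spec(chains = 1L, iterations = 2L,
                                       warmup = 1L)) {
  design <- structure(list(
    X = X, column_names = colnames(X),
    centers = stats::setNames(rep(0, ncol(X)), colnames(X)),
    scales = stats::setNames(rep(1, ncol(X)), colnames(X)),
    group_index = group_index,
    group_levels = unique(group_index),
    theta_hat = theta_hat, sigma_hat = sigma_hat,
    estimate_id = sprintf("obs%d", seq_along(theta_hat))),
    class = "bcmeta_design")
  K <- length(unique(group_index))
  pnames <- c(paste0("b_", colnames(X)),
              sprintf("zeta[%d]", seq_len(K)),
              "sigma_between", "sigma_resid")
  S <- length(draws_list)
  draws <- array(NA_real_, dim = c(S, 1, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  for (s in seq_len(S)) {
    st <- draws_list[[s]]
    draws[s, 1, ] <- c(st$beta, st$zeta, st$sigma_between, st$sigma_resid)
  }
  structure(list(draws = draws, parameters = pnames,
                 diagnostics = data.frame(parameter = pnames,
                                          rhat = 1, ess_bulk = S),
                 design = design, spec = spec, seed = 1L),
            class = "bcmeta_fit")
}

# Quick reduced-settings model spec for tests that need a real MCMC fit.
test_spec <- function(chains = 2L, iterations = 2000L, warmup = 1000L) {
  model_spec(chains = chains, iterations = iterations, warmup = warmup)
}
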