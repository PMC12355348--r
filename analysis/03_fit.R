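#!/usr/bin/env Rscript
# Stage 3: fit the hierarchical meta-regression.
#
# Full model: habitat + climate + method (dummy-coded against
# mangrove/tropical/bayesian) plus centred-and-scaled depth midpoint,
# end-member count and replication, with non-centered study intercepts and
# the known per-estimate sampling SD in the likelihood.  Null model:
# intercept and study intercepts only.  Four chains x 10000 iterations
# (5000 warmup) each, gated on split R-hat <= 1.01 and bulk ESS >= 400.

suppressPackageStartupMessages(library(bcmeta))

seed <- 2024L
adjusted <- utils::read.csv("results/adjusted.csv", stringsAsFactors = FALSE)

full_spec <- model_spec()
null_spec <- model_spec(fixed_effects = character(0))

fit <- fit_mcmc(build_design(adjusted, full_spec), full_spec, seed = seed)
fit_null <- fit_mcmc(build_design(adjusted, null_spec), null_spec,
                     seed = seed + 1L)

summ <- posterior_summary(fit)
utils::write.csv(summ, "results/summary_full.csv", row.names = FALSE)
utils::write.csv(posterior_summary(fit_null), "results/summary_null.csv",
                 row.names = FALSE)

sb <- parameter_draws(fit, "sigma_between")
fold <- fold_variation(sb)
r2 <- bayes_r2(fit)
key <- summ[grepl("^b_|^sigma", summ$parameter), ]

cat("fixed effects and scales (median [95% interval]):\n")
for (i in seq_len(nrow(key))) {
  cat(sprintf("  %-22s %6.2f [%5.2f, %5.2f]\n", key$parameter[i],
              key$median[i], key$q2.5[i], key$q97.5[i]))
}
cat(sprintf("between-study SD %.2f [%.2f, %.2f] -> %.1f-fold variation\n",
            median(sb), quantile(sb, 0.025), quantile(sb, 0.975),
            fold$median))
cat(sprintf("Bayesian R2 %.2f [%.2f, %.2f]\n", r2$median, r2$q2.5, r2$q97.5))
cat(sprintf("diagnostics: max split R-hat %.3f, min bulk ESS %.0f\n",
            max(fit$diagnostics$rhat, na.rm = TRUE),
            min(fit$diagnostics$ess_bulk)))
cat("wrote results/summary_full.csv, results/summary_null.csv\n")
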