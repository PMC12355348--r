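# bcmeta

Bayesian meta-regression of autochthonous vs. allochthonous organic-carbon
sources in coastal wetland ("blue carbon") soils.

## What problem this solves

Saltmarsh, mangrove and seagrass soils sequester globally significant
organic carbon, and a long literature has used tracer mixing models (bulk
δ13C, δ15N, C:N, eDNA, lipids) to ask how much of that carbon comes from the
habitat-forming vegetation itself versus other producers in the connected
seascape. Individual estimates are hard to compare: they differ in habitat,
climate zone, soil depth, replication, number of end-members, modelling
approach, and even in which variability measure they report. `bcmeta` is for
researchers synthesizing such compilations. It provides:

1. **Harmonization** — reported SDs, SEs, 95% CIs and variances are
   converted to adjusted SDs assuming normality.
2. **Effect sizes** — each (mean, adjusted SD) pair is propagated to the
   log-ratio scale `ln(auto/allo)` by 10⁶ draws from a 0–100 truncated
   normal, yielding a per-estimate mean `θ̂ₖ` and known sampling SD `σ̂ₖ`.
3. **Hierarchical meta-regression** — the model

   ```
   θ̂ₖ ~ Normal(μₖ, √(σ̂ₖ² + σ²))
   μₖ  = xₖ'β + ζ_s(k) · σ_between,   ζ_s, β_t ~ Normal(0, 1)
   σ_between, σ ~ Normal(0.5, 0.1) T(0, ∞)
   ```

   with habitat/climate/method dummies (references mangrove, tropical,
   bayesian), centred-and-scaled depth, end-member count and replication,
   non-centered study intercepts grouped by publication, fitted by MCMC
   (4 × 10000 iterations, 5000 warmup) with split-R̂/ESS gates.
4. **Evaluation** — PSIS-LOO comparison against the intercept-only null,
   posterior predictive checks, PIT residuals, Bayesian R².
5. **Source syntheses** — pooled per-source contribution statistics,
   1000-draw bootstrap densities per habitat × source, and two-source
   isotope mixing with delta-method error propagation.
6. **Synthetic evidence base** — a generator reproducing the structure of
   the compiled literature (110 estimates, 78 studies, unbalanced climate,
   depth ≈ 0.20 ± 0.27 m, replication 2–35) with known truth, used by the
   bundled analysis and the parameter-recovery tests.

See `vignettes/bcmeta-methods.Rmd` for the full model description and design
rationale.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the
synthetic evidence base and print their findings; `Rscript
analysis/01_simulate.R` through `05_source_densities.R`. A condensed version
in R:

```r
library(bcmeta)

sim <- generate_compilation(seed = 2024)      # 110 estimates, 78 studies
adj <- batch_logratios(harmonize(sim$records),
                       n_draws = 1e6, master_seed = 2024)
spec <- model_spec()                          # full model, 4 x 10000 MCMC
fit <- fit_mcmc(build_design(adj, spec), spec, seed = 2024)

posterior_summary(fit, "sigma_between")
fold_variation(parameter_draws(fit, "sigma_between"))$median
bayes_r2(fit)
```

Stage 3 of the bundled analysis prints, for the seed-2024 synthetic
compilation:

```
between-study SD 0.59 [0.43, 0.76] -> 3.3-fold variation
Bayesian R2 0.42 [0.30, 0.53]
diagnostics: max split R-hat 1.001, min bulk ESS 1939
```

meaning: after accounting for the design covariates, study identity alone
still moves the autochthonous:allochthonous ratio by a factor of ~3.3 on
average (the generative truth is σ_between = 0.65, partially shrunk by the
informative scale prior — see the vignette), and the model explains ~42% of
the variance in observed log-ratios. Stage 4 compares the full model to the
intercept-only null (elpd difference 6.5 ± 4.2 in favour of the full model)
and stage 5 pools source contributions, e.g. for the seagrass habitat:

```
seagrass  <- seagrass     28.3% +/- 11.5 (n = 56)
seagrass  <- macroalgae   28.2% +/- 11.1 (n = 27)
seagrass  <- mangrove     26.4% +/-  9.9 (n = 27)
```

i.e. in the synthetic evidence base (configured to mirror the pooled
literature values) seagrass meadows derive roughly as much soil carbon from
macroalgae and neighbouring mangroves as from the seagrass itself.

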