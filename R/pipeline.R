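## End-to-end orchestration: ingest (or simulate) -> harmonize -> Monte-Carlo
## log-ratios -> design -> fit full and null models -> evaluate -> source
## densities -> report.  Every output carries the master seed and a hash of
## the configuration; deterministic stages are bit-identical on rerun and
## seeded stochastic stages are draw-identical.

#' Configure an end-to-end pipeline run
#'
#' @param compilation Path to a compilation CSV, or `NULL` to simulate.
#' @param contributions Path to a contributions CSV, or `NULL` (simulated
#'   when `compilation` is `NULL`, skipped otherwise).
#' @param generator A [generator_config()] used when simulating.
#' @param n_draws Monte-Carlo draws per estimate for the log-ratio stage
#'   (default 1e6).
#' @param spec Full-model [model_spec()].
#' @param evaluate Toggles: named logical vector or list with `loo`, `ppc`,
#'   `residuals` (all default `TRUE`).
#' @param n_boot Bootstrap draws per dataset for source densities.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param check_convergence Abort when the fit misses the split R-hat / bulk
#'   ESS gate (default `TRUE`; exploratory short-chain runs may disable it).
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `bcmeta_run_config`.
#' @export
run_config <- function(compilation = NULL, contributions = NULL,
                       generator = generator_config(), n_draws = 1e6,
                       spec = model_spec(),
                       evaluate = c(loo = TRUE, ppc = TRUE, residuals = TRUE),
                       n_boot = 1000L, out_dir = NULL,
                       check_convergence = TRUE, seed) {
  if (missing(seed)) stop_bcmeta("seed is required", class = "bcmeta_arg_error")
  evaluate <- as.list(evaluate)
  structure(list(compilation = compilation, contributions = contributions,
                 generator = generator, n_draws = n_draws, spec = spec,
                 evaluate = evaluate, n_boot = as.integer(n_boot),
                 out_dir = out_dir,
                 check_convergence = isTRUE(check_convergence),
                 seed = as.integer(seed)),
            class = "bcmeta_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order: ingest (or simulate), harmonize,
#' Monte-Carlo log-ratios, design construction, full and null model fits,
#' model evaluation (LOO comparison, posterior predictive checks, PIT
#' residuals), source densities, and a report of the key quantities
#' (fixed-effect posteriors, between-study SD and its fold-variation,
#' Bayesian R-squared, LOO comparison, pooled source statistics, dataset
#' descriptives).  A failed stage aborts with the stage name; outputs
#' produced before the failure are kept in `out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages (default `FALSE`).
#' @return A list of class `bcmeta_report`; see Details in the package
#'   vignette.  When `config$out_dir` is set, CSV/JSON outputs are written
#'   alongside.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "bcmeta_run_config"))
  seed <- config$seed
  cfg_hash <- object_hash(unclass(config))
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[bcmeta %s] %s", stage, paste0(...)))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_bcmeta("pipeline stage '", name, "' failed: ",
                  conditionMessage(e), class = "bcmeta_stage_error")
    })
  }
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  ## -- ingest ---------------------------------------------------------------
  truth <- NULL
  ingest <- stage("ingest", withCallingHandlers({
    if (is.null(config$compilation)) {
      sim <- generate_compilation(config$generator,
                                  seed = substream_seed(seed, "compilation"))
      truth <- sim$truth
      contrib <- generate_source_table(config$generator,
                                       seed = substream_seed(seed, "sources"))
      list(records = sim$records, contributions = contrib, truth = truth)
    } else {
      contrib <- if (!is.null(config$contributions)) {
        read_contributions(config$contributions)
      }
      list(records = read_compilation(config$compilation),
           contributions = contrib, truth = NULL)
    }
  }, warning = note))
  records <- ingest$records
  say("ingest", nrow(records), " estimates from ",
      length(unique(records$study_id)), " studies")

  ## -- harmonize ------------------------------------------------------------
  harmonized <- stage("harmonize",
                      withCallingHandlers(harmonize(records), warning = note))
  emit(harmonized, "harmonized.csv")

  ## -- log-ratios -----------------------------------------------------------
  adjusted <- stage("logratio", withCallingHandlers(
    batch_logratios(harmonized, n_draws = config$n_draws,
                    master_seed = substream_seed(seed, "logratio")),
    warning = note))
  emit(adjusted, "adjusted.csv")
  say("logratio", "propagated ", nrow(adjusted), " estimates at ",
      config$n_draws, " draws each")

  ## -- design + fits --------------------------------------------------------
  full_spec <- config$spec
  null_spec <- model_spec(fixed_effects = character(0),
                          reference_levels = full_spec$reference_levels,
                          prior_coef_sd = full_spec$prior_coef_sd,
                          prior_scale_mean = full_spec$prior_scale_mean,
                          prior_scale_sd = full_spec$prior_scale_sd,
                          chains = full_spec$chains,
                          iterations = full_spec$iterations,
                          warmup = full_spec$warmup,
                          group_by = full_spec$group_by)
  design <- stage("design", withCallingHandlers(
    build_design(adjusted, full_spec), warning = note))
  null_design <- stage("design", withCallingHandlers(
    build_design(adjusted, null_spec), warning = note))
  say("fit", "sampling full model (", full_spec$chains, " chains x ",
      full_spec$iterations, " iterations)")
  fit <- stage("fit_full",
               fit_mcmc(design, full_spec,
                        seed = substream_seed(seed, "fit_full"),
                        check_convergence = config$check_convergence))
  say("fit", "sampling null model")
  fit_null <- stage("fit_null",
                    fit_mcmc(null_design, null_spec,
                             seed = substream_seed(seed, "fit_null"),
                             check_convergence = config$check_convergence))
  summary_full <- posterior_summary(fit)
  emit(summary_full, "summary_full.csv")
  emit(posterior_summary(fit_null), "summary_null.csv")
  emit(draws_long(fit), "draws_full.csv")

  ## -- evaluation -----------------------------------------------------------
  evaluation <- list()
  if (isTRUE(config$evaluate$loo)) {
    evaluation$loo_full <- stage("evaluate", psis_loo(pointwise_loglik(fit)))
    evaluation$loo_null <- stage("evaluate",
                                 psis_loo(pointwise_loglik(fit_null)))
    evaluation$comparison <- compare_elpd(evaluation$loo_full,
                                          evaluation$loo_null)
    emit(data.frame(observation = design$estimate_id,
                    elpd_i = evaluation$loo_full$pointwise,
                    pareto_k = evaluation$loo_full$pareto_k), "loo.csv")
    if (!is.null(out_dir)) {
      jsonlite::write_json(evaluation$comparison,
                           file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (isTRUE(config$evaluate$ppc)) {
    evaluation$ppc <- stage("evaluate", posterior_predictive(
      fit, n_rep = 1000L, seed = substream_seed(seed, "ppc")))
  }
  if (isTRUE(config$evaluate$residuals)) {
    evaluation$pit <- stage("evaluate", pit_residuals(
      fit, seed = substream_seed(seed, "pit")))
  }

  ## -- source densities -----------------------------------------------------
  densities <- NULL
  source_summary <- NULL
  if (!is.null(ingest$contributions)) {
    densities <- stage("densities", habitat_source_densities(
      ingest$contributions, records, n_boot = config$n_boot,
      seed = substream_seed(seed, "densities")))
    source_summary <- attr(densities, "summary")
    emit(source_summary, "source_summary.csv")
    emit(do.call(rbind, lapply(names(densities), function(k) {
      d <- densities[[k]]
      data.frame(cell = k, grid_point = d$grid, density = d$density)
    })), "densities.csv")
  }

  ## -- report ---------------------------------------------------------------
  sb <- pooled_draws(fit)[, "sigma_between"]
  fold <- fold_variation(sb)
  r2 <- bayes_r2(fit)
  descriptives <- list(
    n_estimates = nrow(records),
    n_studies = length(unique(records$study_id)),
    mean_depth_mid_m = mean(records$depth_mid_m),
    sd_depth_mid_m = stats::sd(records$depth_mid_m),
    median_replicates = stats::median(records$n_replicates),
    tropical_pct_by_habitat = vapply(
      split(records$climate == "tropical", records$habitat), function(x)
        100 * mean(x), 0))
  report <- structure(list(
    seed = seed, config_hash = cfg_hash,
    descriptives = descriptives,
    summary_full = summary_full,
    sigma_between = stats::quantile(sb, c(0.025, 0.5, 0.975), names = FALSE),
    fold_variation = fold[c("median", "q2.5", "q97.5")],
    bayes_r2 = r2[c("median", "q2.5", "q97.5")],
    evaluation = evaluation,
    source_summary = source_summary,
    densities = densities,
    fit = fit, fit_null = fit_null,
    adjusted = adjusted, records = records,
    truth = ingest$truth,
    warnings = warnings_log), class = "bcmeta_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(seed = seed, config_hash = cfg_hash,
                              descriptives = descriptives,
                              sigma_between = report$sigma_between,
                              fold_variation = report$fold_variation,
                              bayes_r2 = report$bayes_r2,
                              warnings = warnings_log),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("report", "sigma_between median ",
      sprintf("%.3f", report$sigma_between[2]),
      " (fold-variation ", sprintf("%.2f", fold$median), ")")
  report
}

## long-format draws table (chain, iteration, parameter, value)
draws_long <- function(fit) {
  d <- fit$draws
  dims <- dim(d)
  data.frame(chain = rep(rep(seq_len(dims[2]), each = dims[1]), dims[3]),
             iteration = rep(seq_len(dims[1]), dims[2] * dims[3]),
             parameter = rep(dimnames(d)[[3]], each = dims[1] * dims[2]),
             value = as.vector(d))
}
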