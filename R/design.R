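## Fixed-effect design construction for the meta-regression.

CONTINUOUS_EFFECTS <- c("depth_mid_m", "n_endmembers", "n_replicates")
CATEGORICAL_EFFECTS <- c("habitat", "climate", "method")

#' Specify the meta-regression model
#'
#' Collects the fixed-effect structure, reference levels, priors and MCMC
#' settings for the hierarchical meta-regression.  The default is the full
#' model: habitat, climate and mixing-model method as dummy-coded categorical
#' effects (references mangrove / tropical / bayesian) plus centred-and-scaled
#' depth midpoint, number of end-members and replication.  `fixed_effects =
#' character(0)` gives the null (intercept-only) model, which keeps the study
#' random intercept and the known measurement-error term.
#'
#' Priors are weakly informative on the scale of the data: Normal(0, 1) on
#' all coefficients (including the intercept) and standardized study effects,
#' and Normal(0.5, 0.1) truncated to positive values on the between-study and
#' residual SDs.
#'
#' @param fixed_effects Character vector drawn from
#'   `c("habitat", "climate", "method", "depth_mid_m", "n_endmembers",
#'   "n_replicates")`.
#' @param reference_levels Named list of reference levels for the categorical
#'   effects.
#' @param prior_coef_sd SD of the normal prior on coefficients and
#'   standardized study effects.
#' @param prior_scale_mean,prior_scale_sd Location and SD of the positive
#'   truncated-normal prior on the two scale parameters.
#' @param chains,iterations,warmup MCMC settings: number of parallel chains,
#'   total iterations per chain, and warmup iterations discarded from the
#'   start of each chain (defaults 4 / 10000 / 5000, i.e. 20000 posterior
#'   draws).
#' @param group_by Grouping for the random intercept: `"study"` (publication,
#'   default) or `"estimate"`.
#' @return An object of class `bcmeta_model_spec`.
#' @examples
#' model_spec()                       # full model
#' model_spec(fixed_effects = character(0))  # null model
#' @export
model_spec <- function(fixed_effects = c(CATEGORICAL_EFFECTS,
                                         CONTINUOUS_EFFECTS),
                       reference_levels = list(habitat = "mangrove",
                                               climate = "tropical",
                                               method = "bayesian"),
                       prior_coef_sd = 1,
                       prior_scale_mean = 0.5,
                       prior_scale_sd = 0.1,
                       chains = 4L, iterations = 10000L, warmup = 5000L,
                       group_by = c("study", "estimate")) {
  group_by <- match.arg(group_by)
  bad <- setdiff(fixed_effects, c(CATEGORICAL_EFFECTS, CONTINUOUS_EFFECTS))
  if (length(bad) > 0L) {
    stop_bcmeta("unknown fixed effect(s): ", paste(bad, collapse = ", "),
                class = "bcmeta_arg_error")
  }
  vocab <- list(habitat = HABITATS, climate = CLIMATES, method = METHODS)
  for (v in names(reference_levels)) {
    if (!reference_levels[[v]] %in% vocab[[v]]) {
      stop_bcmeta("reference level for ", v, " must be one of ",
                  paste(vocab[[v]], collapse = ", "),
                  class = "bcmeta_arg_error")
    }
  }
  if (warmup >= iterations) {
    stop_bcmeta("warmup must be smaller than iterations",
                class = "bcmeta_arg_error")
  }
  structure(list(fixed_effects = fixed_effects,
                 reference_levels = reference_levels,
                 prior_coef_sd = prior_coef_sd,
                 prior_scale_mean = prior_scale_mean,
                 prior_scale_sd = prior_scale_sd,
                 chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 group_by = group_by),
            class = "bcmeta_model_spec")
}

#' Build the fixed-effects design matrix
#'
#' Dummy-codes the categorical covariates against the spec's reference levels
#' and centres/scales the continuous covariates by their in-sample mean and
#' SD (stored for reuse at prediction time).  The first column is the
#' intercept.  Dummy columns with zero variance (a level absent from the
#' data) are dropped with a warning; a zero-variance continuous column is an
#' error naming the column.
#'
#' @param estimates Adjusted-estimate `data.frame` from [batch_logratios()].
#' @param spec A [model_spec()].
#' @return A list of class `bcmeta_design`: `X` (n x T matrix, first column
#'   intercept), `column_names`, `centers`, `scales`, `group_index` (integer
#'   vector mapping observations to groups), `group_levels`, `theta_hat`,
#'   `sigma_hat`, `estimate_id`.
#' @export
build_design <- function(estimates, spec = model_spec()) {
  stopifnot(inherits(spec, "bcmeta_model_spec"))
  needed <- c("estimate_id", "study_id", "logratio_mean", "logratio_sd",
              intersect(spec$fixed_effects,
                        c(CATEGORICAL_EFFECTS, CONTINUOUS_EFFECTS)))
  missing <- setdiff(needed, names(estimates))
  if (length(missing) > 0L) {
    stop_bcmeta("estimates are missing column(s): ",
                paste(missing, collapse = ", "), class = "bcmeta_arg_error")
  }
  n <- nrow(estimates)
  group_var <- if (spec$group_by == "study") estimates$study_id else
    estimates$estimate_id
  group_levels <- unique(group_var)
  if (length(group_levels) < 2L) {
    stop_bcmeta("need at least 2 distinct groups (studies)",
                class = "bcmeta_arg_error")
  }
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "intercept"))
  centers <- c(intercept = 0)
  scales <- c(intercept = 1)
  vocab <- list(habitat = HABITATS, climate = CLIMATES, method = METHODS)
  for (v in intersect(CATEGORICAL_EFFECTS, spec$fixed_effects)) {
    vals <- normalize_enum(estimates[[v]], vocab[[v]], v)
    ref <- spec$reference_levels[[v]]
    for (lev in setdiff(vocab[[v]], ref)) {
      col <- as.numeric(vals == lev)
      nm <- paste0(v, "_", lev)
      if (stats::var(col) == 0) {
        warning("dropping zero-variance dummy column '", nm, "'",
                call. = FALSE)
        next
      }
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- nm
      centers[nm] <- 0
      scales[nm] <- 1
    }
  }
  for (v in intersect(CONTINUOUS_EFFECTS, spec$fixed_effects)) {
    x <- as.numeric(estimates[[v]])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop_bcmeta("continuous column '", v, "' has zero variance",
                  class = "bcmeta_arg_error")
    }
    m <- mean(x)
    X <- cbind(X, (x - m) / s)
    colnames(X)[ncol(X)] <- v
    centers[v] <- m
    scales[v] <- s
  }
  structure(list(X = X,
                 column_names = colnames(X),
                 centers = centers,
                 scales = scales,
                 group_index = match(group_var, group_levels),
                 group_levels = group_levels,
                 theta_hat = estimates$logratio_mean,
                 sigma_hat = estimates$logratio_sd,
                 estimate_id = estimates$estimate_id),
            class = "bcmeta_design")
}
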