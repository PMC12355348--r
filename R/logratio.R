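## Monte-Carlo propagation of reported (mean, adjusted SD) pairs to the
## log-ratio effect-size scale ln(auto / allo).
##
## Each estimate's autochthonous percentage a is treated as Normal(mean, sd)
## truncated to the open interval (0, 100); allochthonous carbon is 100 - a,
## and the effect size is the mean and SD of ln(a / (100 - a)) over the draws.

#' Propagate one estimate to the log-ratio scale by Monte Carlo
#'
#' Draws `n_draws` values of the autochthonous percentage from a
#' Normal(`auto_mean_pct`, `adjusted_sd_pct`) truncated to (0, 100), computes
#' the allochthonous complement `100 - a`, and summarizes
#' `ln(a / (100 - a))` by its mean and SD.  Sampling is by inverse-CDF
#' transform; draws that fall on 0 or 100 in floating point are redrawn so the
#' logarithm stays finite without biasing the open interval.
#'
#' Autochthonous means of exactly 0 or 100 are clamped to 0.1 / 99.9 with a
#' warning; a non-positive `adjusted_sd_pct` degenerates to the point-mass
#' log-ratio with `sd = 0` and `degenerate = TRUE`.
#'
#' @param auto_mean_pct Reported autochthonous mean, percent.
#' @param adjusted_sd_pct Adjusted SD, percentage points.
#' @param n_draws Number of Monte-Carlo draws (default 1e6).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A list with `mean`, `sd`, `n_draws`, `seed`, `degenerate`,
#'   `clamped`.
#' @examples
#' sample_logratio(75, 5, n_draws = 1e4, seed = 1)
#' @export
sample_logratio <- function(auto_mean_pct, adjusted_sd_pct,
                            n_draws = 1e6, seed) {
  stopifnot(length(auto_mean_pct) == 1L, length(adjusted_sd_pct) == 1L)
  if (missing(seed)) stop_bcmeta("seed is required", class = "bcmeta_arg_error")
  clamped <- FALSE
  m <- clamp_auto_mean(auto_mean_pct)
  clamped <- !identical(m, auto_mean_pct)
  if (m <= 0 || m >= 100) {
    stop_bcmeta("auto_mean_pct must lie in (0, 100) after clamping",
                class = "bcmeta_arg_error")
  }
  if (adjusted_sd_pct <= 0) {
    return(list(mean = log(m / (100 - m)), sd = 0, n_draws = 0L,
                seed = as.integer(seed), degenerate = TRUE,
                clamped = clamped))
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  a <- rtruncnorm(n_draws, m, adjusted_sd_pct, 0, 100)
  lr <- log(a / (100 - a))
  list(mean = mean(lr), sd = stats::sd(lr), n_draws = as.integer(n_draws),
       seed = as.integer(seed), degenerate = FALSE, clamped = clamped)
}

clamp_auto_mean <- function(m) {
  if (m == 0) {
    warning("autochthonous mean of 0% clamped to 0.1%", call. = FALSE)
    return(0.1)
  }
  if (m == 100) {
    warning("autochthonous mean of 100% clamped to 99.9%", call. = FALSE)
    return(99.9)
  }
  m
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Deterministic quadrature oracle for the truncated-normal log-ratio
#'
#' Computes the exact mean and SD of `ln(a / (100 - a))` when `a` follows a
#' Normal(`auto_mean_pct`, `adjusted_sd_pct`) truncated to (0, 100), by
#' adaptive numerical integration.  Intended as an independent check on
#' [sample_logratio()]; it is not used in the pipeline itself.
#'
#' @inheritParams sample_logratio
#' @return A list with `mean` and `sd`.
#' @export
logratio_oracle <- function(auto_mean_pct, adjusted_sd_pct) {
  m <- clamp_auto_mean(auto_mean_pct)
  s <- adjusted_sd_pct
  if (s <= 0) return(list(mean = log(m / (100 - m)), sd = 0))
  z <- stats::pnorm(100, m, s) - stats::pnorm(0, m, s)
  dens <- function(a) stats::dnorm(a, m, s) / z
  ## all non-negligible mass lies within +/- 15 sd of the mode; restricting
  ## the range keeps adaptive quadrature from missing narrow spikes
  lo0 <- max(0, m - 15 * s)
  hi0 <- min(100, m + 15 * s)
  mid <- min(max(m, lo0 + 1e-12), hi0 - 1e-12)
  moment <- function(fun) {
    f <- function(a) fun(log(a / (100 - a))) * dens(a)
    lo <- stats::integrate(f, lo0, mid,
                           rel.tol = 1e-10, abs.tol = 1e-12,
                           subdivisions = 400L)
    hi <- stats::integrate(f, mid, hi0,
                           rel.tol = 1e-10, abs.tol = 1e-12,
                           subdivisions = 400L)
    if (lo$message != "OK" || hi$message != "OK") {
      stop_bcmeta("quadrature failed to converge",
                  class = "bcmeta_quadrature_error")
    }
    lo$value + hi$value
  }
  mu <- moment(identity)
  m2 <- moment(function(x) x^2)
  list(mean = mu, sd = sqrt(max(m2 - mu^2, 0)))
}

#' Batch Monte-Carlo log-ratio computation
#'
#' Applies [sample_logratio()] to every row of a harmonized compilation.  Each
#' estimate gets an independent RNG substream keyed by `(master_seed,
#' estimate_id)`, so results do not depend on row order and subsets reproduce
#' the full run.
#'
#' @param records A harmonized compilation (output of [harmonize()]).
#' @param n_draws Monte-Carlo draws per estimate (default 1e6).
#' @param master_seed Integer master seed.
#' @return A `data.frame` of adjusted estimates: ids, covariates,
#'   `logratio_mean`, `logratio_sd`, `n_draws`, `seed`, `degenerate`.
#' @examples
#' comp <- harmonize(generate_compilation(seed = 1)$records)
#' adj <- batch_logratios(comp[1:5, ], n_draws = 1e4, master_seed = 7)
#' adj[, c("estimate_id", "logratio_mean", "logratio_sd")]
#' @export
batch_logratios <- function(records, n_draws = 1e6, master_seed) {
  if (missing(master_seed)) {
    stop_bcmeta("master_seed is required", class = "bcmeta_arg_error")
  }
  if (!"adjusted_sd_pct" %in% names(records)) {
    stop_bcmeta("records must be harmonized first (missing adjusted_sd_pct)",
                class = "bcmeta_arg_error")
  }
  n <- nrow(records)
  out <- records[c("estimate_id", "study_id", "habitat", "climate", "method",
                   "depth_mid_m", "n_endmembers", "n_replicates")]
  out$logratio_mean <- rep(NA_real_, n)
  out$logratio_sd <- rep(NA_real_, n)
  out$n_draws <- rep(NA_integer_, n)
  out$seed <- rep(NA_integer_, n)
  out$degenerate <- rep(FALSE, n)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    sseed <- substream_seed(master_seed, records$estimate_id[i])
    res <- tryCatch(
      sample_logratio(records$auto_mean_pct[i], records$adjusted_sd_pct[i],
                      n_draws = n_draws, seed = sseed),
      error = function(e) {
        stop_bcmeta("estimate '", records$estimate_id[i], "': ",
                    conditionMessage(e), class = "bcmeta_row_error")
      })
    out$logratio_mean[i] <- res$mean
    out$logratio_sd[i] <- res$sd
    out$n_draws[i] <- res$n_draws
    out$seed[i] <- res$seed
    out$degenerate[i] <- res$degenerate
  }
  out
}
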