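## Reading, validating and harmonizing the source-estimate compilation.
##
## The unit of the compilation is one habitat-specific independent estimate of
## the autochthonous share of soil organic carbon, with covariates describing
## how it was obtained and a reported variability measure of heterogeneous
## type (SD, SE, 95% CI or variance) that must be converted to an "adjusted
## SD" on the percentage scale before any effect-size computation.

HABITATS <- c("saltmarsh", "mangrove", "seagrass")
CLIMATES <- c("tropical", "temperate")
METHODS  <- c("standard", "bayesian", "other")
VAR_KINDS <- c("sd", "se", "ci95", "variance")

COMPILATION_COLUMNS <- c("estimate_id", "study_id", "habitat", "climate",
                         "method", "depth_mid_m", "n_endmembers",
                         "n_replicates", "auto_mean_pct", "var_kind",
                         "var_a", "var_b")

CONTRIBUTION_COLUMNS <- c("estimate_id", "source_name", "mean_pct", "sd_pct",
                          "n_estimates")

normalize_enum <- function(x, levels, column) {
  x <- tolower(trimws(as.character(x)))
  bad <- which(!x %in% levels & !is.na(x))
  if (length(bad) > 0L) {
    stop_bcmeta("column '", column, "' has value(s) outside {",
                paste(levels, collapse = ", "), "} at row(s) ",
                paste(utils::head(bad, 5L), collapse = ", "),
                class = "bcmeta_row_error")
  }
  x
}

#' Read a soil-carbon source compilation
#'
#' Reads the estimate-level compilation table (CSV, one row per independent
#' habitat-specific estimate) and validates it against the documented schema:
#' columns `estimate_id, study_id, habitat, climate, method, depth_mid_m,
#' n_endmembers, n_replicates, auto_mean_pct, var_kind, var_a, var_b`.
#' Categorical fields are normalized case-insensitively to the closed
#' vocabularies (habitat: saltmarsh/mangrove/seagrass; climate:
#' tropical/temperate; method: standard/bayesian/other; var_kind:
#' sd/se/ci95/variance).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A `data.frame` with one row per estimate, columns as above,
#'   enum columns normalized, and numeric columns coerced to numeric.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_compilation(generate_compilation(seed = 1)$records, f)
#' head(read_compilation(f))
#' @export
read_compilation <- function(path) {
  if (!file.exists(path)) {
    stop_bcmeta("compilation file not found: ", path, class = "bcmeta_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(COMPILATION_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop_bcmeta("compilation is missing required column(s): ",
                paste(missing, collapse = ", "), class = "bcmeta_schema_error")
  }
  df <- df[COMPILATION_COLUMNS]
  validate_compilation(df)
}

#' @rdname read_compilation
#' @param records A compilation `data.frame` as returned by
#'   [read_compilation()] or [generate_compilation()].
#' @export
write_compilation <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records[COMPILATION_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate a compilation data frame
#'
#' Checks the schema, normalizes the categorical vocabularies and enforces the
#' row-level invariants: unique estimate ids, finite autochthonous means in
#' \[0, 100\], non-negative dispersion values, and for 95% CIs an upper bound
#' strictly above the lower.  Autochthonous means of exactly 0 or 100 are
#' accepted but flagged with a warning (the log-ratio stage clamps them).
#'
#' @param df A data.frame with the compilation columns.
#' @return The validated, normalized data.frame (row order preserved).
#' @export
validate_compilation <- function(df) {
  missing <- setdiff(COMPILATION_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop_bcmeta("compilation is missing required column(s): ",
                paste(missing, collapse = ", "), class = "bcmeta_schema_error")
  }
  df$estimate_id <- as.character(df$estimate_id)
  df$study_id <- as.character(df$study_id)
  if (anyDuplicated(df$estimate_id)) {
    stop_bcmeta("estimate_id values are not unique",
                class = "bcmeta_row_error")
  }
  df$habitat <- normalize_enum(df$habitat, HABITATS, "habitat")
  df$climate <- normalize_enum(df$climate, CLIMATES, "climate")
  df$method <- normalize_enum(df$method, METHODS, "method")
  df$var_kind <- normalize_enum(df$var_kind, VAR_KINDS, "var_kind")
  for (col in c("depth_mid_m", "n_endmembers", "n_replicates",
                "auto_mean_pct", "var_a", "var_b")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(!is.finite(df$auto_mean_pct) | df$auto_mean_pct < 0 |
          df$auto_mean_pct > 100)) {
    stop_bcmeta("auto_mean_pct must be finite and within [0, 100]",
                class = "bcmeta_row_error")
  }
  if (any(df$depth_mid_m < 0, na.rm = TRUE)) {
    stop_bcmeta("depth_mid_m must be >= 0", class = "bcmeta_row_error")
  }
  if (any(df$n_endmembers < 2 | df$n_replicates < 2)) {
    stop_bcmeta("n_endmembers and n_replicates must be >= 2",
                class = "bcmeta_row_error")
  }
  notci <- df$var_kind != "ci95"
  if (any(df$var_a[notci] < 0)) {
    stop_bcmeta("var_a must be >= 0 for sd/se/variance measures",
                class = "bcmeta_row_error")
  }
  ci <- which(df$var_kind == "ci95")
  if (length(ci) > 0L && any(!is.finite(df$var_b[ci]) |
                             df$var_b[ci] <= df$var_a[ci])) {
    stop_bcmeta("ci95 rows need var_b (upper bound) > var_a (lower bound)",
                class = "bcmeta_row_error")
  }
  boundary <- df$auto_mean_pct %in% c(0, 100)
  if (any(boundary)) {
    warning(sum(boundary), " estimate(s) report an autochthonous mean of ",
            "exactly 0 or 100%; they will be clamped at the log-ratio stage",
            call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a per-source contribution table
#'
#' Companion table to the compilation: one row per (estimate, carbon source)
#' with the mixing-model mean and SD of that source's contribution to the soil
#' organic-carbon mixture, in percent.
#'
#' @param path Path to a UTF-8 CSV with columns `estimate_id, source_name,
#'   mean_pct, sd_pct, n_estimates`.
#' @return A validated `data.frame`.
#' @export
read_contributions <- function(path) {
  if (!file.exists(path)) {
    stop_bcmeta("contributions file not found: ", path,
                class = "bcmeta_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(CONTRIBUTION_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop_bcmeta("contributions table is missing required column(s): ",
                paste(missing, collapse = ", "), class = "bcmeta_schema_error")
  }
  df <- df[CONTRIBUTION_COLUMNS]
  df$source_name <- tolower(trimws(df$source_name))
  for (col in c("mean_pct", "sd_pct", "n_estimates")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$mean_pct < 0 | df$mean_pct > 100) || any(df$sd_pct < 0) ||
      any(df$n_estimates < 1)) {
    stop_bcmeta("contribution rows need mean_pct in [0,100], sd_pct >= 0, ",
                "n_estimates >= 1", class = "bcmeta_row_error")
  }
  df
}

#' Convert a standard error to a standard deviation
#'
#' Reported standard errors of a mean over `n` spatial replicates are converted
#' back to the sample standard deviation, `sd = se * sqrt(n)`.
#'
#' @param se Standard error (percentage points), `>= 0`.
#' @param n Number of replicates underlying the mean, `>= 1`.
#' @return Standard deviation on the same scale.
#' @examples
#' se_to_sd(2, 4)  # 4
#' @export
se_to_sd <- function(se, n) {
  if (any(n < 1)) stop_bcmeta("n must be >= 1", class = "bcmeta_arg_error")
  if (any(se < 0)) stop_bcmeta("se must be >= 0", class = "bcmeta_arg_error")
  se * sqrt(n)
}

#' Convert a normal confidence interval to a standard deviation
#'
#' Assumes the reported interval is a normal CI of a mean over `n` replicates:
#' `sd = sqrt(n) * (upper - lower) / (2 * z)` with `z` the standard-normal
#' quantile at `(1 + level) / 2`.
#'
#' @param lower,upper CI bounds (percentage points), `upper > lower`.
#' @param n Number of replicates underlying the mean.
#' @param level Nominal coverage of the interval (default 0.95).
#' @return Standard deviation on the percentage scale.
#' @examples
#' ci_to_sd(40, 60, n = 4)  # about 10.2
#' @export
ci_to_sd <- function(lower, upper, n, level = 0.95) {
  if (any(n < 1)) stop_bcmeta("n must be >= 1", class = "bcmeta_arg_error")
  if (any(level <= 0 | level >= 1)) {
    stop_bcmeta("level must be in (0, 1)", class = "bcmeta_arg_error")
  }
  if (any(upper <= lower)) {
    stop_bcmeta("upper CI bound must exceed lower bound",
                class = "bcmeta_arg_error")
  }
  z <- stats::qnorm((1 + level) / 2)
  sqrt(n) * (upper - lower) / (2 * z)
}

#' Harmonize reported variability measures to adjusted SDs
#'
#' Converts each estimate's reported variability measure into a standard
#' deviation on the percentage scale (the "adjusted SD"), assuming normality:
#' `sd` passes through, `se` is multiplied by `sqrt(n_replicates)`, `ci95` uses
#' [ci_to_sd()] with `n_replicates`, and `variance` is square-rooted.  Any
#' other kind is rejected rather than guessed.
#'
#' @param records A validated compilation `data.frame`.
#' @return The input with an `adjusted_sd_pct` column appended.
#' @examples
#' comp <- generate_compilation(seed = 1)$records
#' harmonized <- harmonize(comp)
#' summary(harmonized$adjusted_sd_pct)
#' @export
harmonize <- function(records) {
  records <- validate_compilation(records)
  k <- records$var_kind
  out <- rep(NA_real_, nrow(records))
  out[k == "sd"] <- records$var_a[k == "sd"]
  out[k == "se"] <- se_to_sd(records$var_a[k == "se"],
                             records$n_replicates[k == "se"])
  out[k == "variance"] <- sqrt(records$var_a[k == "variance"])
  ci <- k == "ci95"
  if (any(ci)) {
    out[ci] <- ci_to_sd(records$var_a[ci], records$var_b[ci],
                        records$n_replicates[ci])
  }
  if (anyNA(out)) {
    stop_bcmeta("unknown variability kind in rows ",
                paste(which(is.na(out)), collapse = ", "),
                class = "bcmeta_row_error")
  }
  records$adjusted_sd_pct <- out
  records
}
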