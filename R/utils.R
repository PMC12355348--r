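#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Deterministic 31-bit hash of a character key combined with an integer master
## seed, used to derive independent per-record RNG substreams keyed by id (not
## position).  FNV-1a style rolling hash kept within double-exact integer range.
substream_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  h <- (as.numeric(master_seed) %% 2147483647) + 16777619
  bytes <- utf8ToInt(paste0("s:", key))
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

## Draws from Normal(mean, sd) truncated to (lower, upper) by inverse-CDF.
## Draws that land exactly on a bound in floating point are redrawn uniformly
## within the open probability interval, keeping the support strictly open.
rtruncnorm <- function(n, mean, sd, lower = 0, upper = 100) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) {
    stop("truncated-normal interval has no probability mass for mean = ",
         mean, ", sd = ", sd)
  }
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0L) {
    u2 <- stats::runif(length(bad), plo, phi)
    x[bad] <- stats::qnorm(u2, mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

## Short stable hash of an arbitrary R object (config fingerprinting).
object_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames",
                                      "showAttributes")), collapse = "\n")
  h1 <- substream_seed(1L, txt)
  h2 <- substream_seed(2L, txt)
  sprintf("%08x%08x", h1, h2)
}

stop_bcmeta <- function(..., class) {
  stop(structure(class = c(class, "bcmeta_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
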