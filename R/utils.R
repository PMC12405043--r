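# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library functions never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Round half away from zero; used wherever seconds are converted to sample
# counts so results are bit-stable across sampling rates.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic per-trial seed derived from a base seed and integer indices.
# Kept below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Coefficient of variation in percent. Returns NA for fewer than 2 values.
cv_pct <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
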