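# Bootstrap group statistics: percentile CIs for mean differences and
# Cohen's d effect sizes with the conventional magnitude labels.

#' Percentile bootstrap CI for a group mean difference
#'
#' Resamples each group independently with replacement `n` times and builds
#' the percentile 95% CI of `mean(a*) - mean(b*)`. Inference is by CI: a
#' difference is read as significant when the interval excludes zero (no
#' p-values).
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param n number of bootstrap resamples (default 10000).
#' @param seed integer seed; the CI is deterministic per seed.
#' @param conf confidence level.
#' @return An object of class `boot_result` with `estimate`, `ci`,
#'   `n_resamples`, `seed` and `significant` (CI excludes 0).
#' @export
boot_mean_diff <- function(a, b, n = 10000, seed = 1L, conf = 0.95) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("each group needs at least 2 observations")
  }
  est <- mean(a) - mean(b)
  ci <- with_seed(seed, {
    am <- matrix(sample(a, n * length(a), replace = TRUE), nrow = n)
    bm <- matrix(sample(b, n * length(b), replace = TRUE), nrow = n)
    diffs <- rowMeans(am) - rowMeans(bm)
    unname(stats::quantile(diffs, c((1 - conf) / 2, (1 + conf) / 2)))
  })
  structure(list(estimate = est, ci = c(lower = ci[1], upper = ci[2]),
                 n_resamples = n, seed = seed,
                 significant = ci_excludes_zero(ci)),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("Mean difference %.3f, 95%% CI [%.3f, %.3f]%s (%d resamples)\n",
              x$estimate, x$ci[1], x$ci[2],
              if (x$significant) " *" else "", x$n_resamples))
  invisible(x)
}

#' Does a confidence interval exclude zero?
#'
#' The package's significance rule: an effect is read as significant when
#' its CI's bounds lie on the same side of zero.
#'
#' @param ci numeric length-2 interval `c(lower, upper)`.
#' @return logical.
#' @export
ci_excludes_zero <- function(ci) {
  ci[1] > 0 || ci[2] < 0
}

#' Bootstrapped Cohen's d with magnitude label
#'
#' Point estimate `d = (mean(a) - mean(b)) / pooled SD`, a percentile
#' bootstrap CI, and the conventional magnitude label from [classify_d()].
#'
#' @inheritParams boot_mean_diff
#' @return An object of class `effect_size` with `d`, `ci`, `label`.
#' @export
boot_cohens_d <- function(a, b, n = 10000, seed = 1L, conf = 0.95) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("each group needs at least 2 observations")
  }
  d_of <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / sp
  }
  d <- d_of(a, b)
  if (!is.finite(d)) stop_invalid("zero pooled SD")
  ci <- with_seed(seed, {
    ds <- vapply(seq_len(n), function(i) {
      d_of(sample(a, replace = TRUE), sample(b, replace = TRUE))
    }, numeric(1))
    ds <- ds[is.finite(ds)]
    unname(stats::quantile(ds, c((1 - conf) / 2, (1 + conf) / 2)))
  })
  structure(list(d = d, ci = c(lower = ci[1], upper = ci[2]),
                 label = classify_d(d), n_resamples = n, seed = seed),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (%s), 95%% CI [%.2f, %.2f]\n",
              x$d, x$label, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Effect-size magnitude label
#'
#' Maps `|d|` to the conventional taxonomy: trivial `[0, 0.2)`, small
#' `[0.2, 0.5)`, moderate `[0.5, 0.8)`, large `[0.8, Inf)`. Intervals are
#' half-open, so boundary values take the upper class.
#'
#' @param d Cohen's d (sign ignored).
#' @return one of `"trivial"`, `"small"`, `"moderate"`, `"large"`.
#' @export
classify_d <- function(d) {
  cut(abs(d), breaks = c(0, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("trivial", "small", "moderate", "large"),
      include.lowest = TRUE) |> as.character()
}
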