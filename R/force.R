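# Force steadiness metrics: MVC extraction, target-referenced coefficient of
# variation, steadiest-window search, and the peak-force-vs-COV regression.

#' Force trace container
#'
#' @param samples numeric force series, newtons.
#' @param fs sampling rate, Hz.
#' @param target scalar target force for the hold, newtons (> 0 for
#'   submaximal trials).
#' @param level target as a fraction of MVC (optional, for bookkeeping).
#' @param ramp_s,hold_s,pre_s protocol timestamps locating the hold within
#'   the trace: the hold spans `[pre_s + ramp_s, pre_s + ramp_s + hold_s]`.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(samples, fs, target, level = NA_real_,
                        ramp_s = 2, hold_s = 10, pre_s = 0) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop_invalid("`samples` must be a numeric series")
  }
  if (!is_scalar_num(fs) || fs <= 0) stop_invalid("`fs` must be > 0")
  if (!is_scalar_num(target)) stop_invalid("`target` must be a number")
  hold_end <- pre_s + ramp_s + hold_s
  if (hold_end > length(samples) / fs + 1e-9) {
    stop_invalid("hold window extends beyond the trace")
  }
  structure(list(samples = as.numeric(samples), fs = fs, target = target,
                 level = level, ramp_s = ramp_s, hold_s = hold_s,
                 pre_s = pre_s),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %.1f s at %g Hz, target %.1f N\n",
              length(x$samples) / x$fs, x$fs, x$target))
  invisible(x)
}

#' Maximal voluntary contraction from a set of maximal-effort traces
#'
#' @param traces list of [force_trace()] objects (or numeric vectors).
#' @return the global maximum force sample across all traces, newtons.
#' @export
compute_mvc <- function(traces) {
  if (length(traces) < 1L) stop_invalid("need at least one trace")
  if (inherits(traces, "force_trace") || is.numeric(traces)) {
    traces <- list(traces)
  }
  max(vapply(traces, function(tr) {
    s <- if (inherits(tr, "force_trace")) tr$samples else tr
    max(s)
  }, numeric(1)))
}

#' Target-referenced force steadiness over the central hold
#'
#' The coefficient of variation of force, referenced to the target force
#' (not the observed mean), over the 6 s centered on the midpoint of the
#' steady hold.
#'
#' @param trace a [force_trace()] whose hold lasts at least `center_s`.
#' @param center_s width of the central analysis window, seconds.
#' @return COV in percent of target.
#' @export
steadiness_cov <- function(trace, center_s = 6) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$hold_s < center_s) {
    stop_invalid("hold must last at least ", center_s, " s")
  }
  if (trace$target <= 0) stop_invalid("target must be > 0")
  mid <- trace$pre_s + trace$ramp_s + trace$hold_s / 2
  i0 <- round_half_up((mid - center_s / 2) * trace$fs) + 1
  i1 <- i0 + round_half_up(center_s * trace$fs) - 1
  i1 <- min(i1, length(trace$samples))
  100 * stats::sd(trace$samples[i0:i1]) / trace$target
}

#' Steadiest fixed-width window of a force trace
#'
#' Slides a window of `width` seconds in `step`-second increments over the
#' whole trace and returns the window with the smallest target-referenced
#' COV; ties are broken by the earliest start. Ramp portions self-exclude by
#' their huge target-referenced variability.
#'
#' @param trace a [force_trace()].
#' @param width window width, seconds (default 4).
#' @param step slide increment, seconds (default 0.05).
#' @return An object of class `steady_window` with fields `start` (s),
#'   `width` (s) and `cov` (% of target).
#' @export
find_steadiest_window <- function(trace, width = 4, step = 0.05) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$samples)
  w <- as.integer(round_half_up(width * trace$fs))
  s <- max(1L, as.integer(round_half_up(step * trace$fs)))
  if (w > n) stop_invalid("trace is shorter than the window")
  starts <- seq.int(1L, n - w + 1L, by = s)
  # windowed SD via cumulative sums
  x <- trace$samples
  c1 <- cumsum(c(0, x))
  c2 <- cumsum(c(0, x^2))
  sums <- c1[starts + w] - c1[starts]
  sqs <- c2[starts + w] - c2[starts]
  sds <- sqrt(pmax(0, (sqs - sums^2 / w) / (w - 1)))
  covs <- 100 * sds / trace$target
  best <- which.min(covs)  # earliest index on ties
  structure(list(start = (starts[best] - 1) / trace$fs, width = width,
                 cov = covs[best]),
            class = "steady_window")
}

#' @export
print.steady_window <- function(x, ...) {
  cat(sprintf("Steadiest window: %.2f-%.2f s, COV %.2f%% of target\n",
              x$start, x$start + x$width, x$cov))
  invisible(x)
}

#' Normalize force capacity to an anthropometric size measure
#'
#' @param peak peak force, newtons.
#' @param size anthropometric size (e.g. forearm circumference or muscle
#'   thickness), millimetres; must be > 0.
#' @return peak / size, N per mm.
#' @export
normalize_capacity <- function(peak, size) {
  if (any(size <= 0)) stop_invalid("`size` must be > 0")
  peak / size
}

#' Ordinary least squares of steadiness on peak force
#'
#' Fits `cov ~ peak` by OLS and reports the intercept, the slope with its
#' 95% confidence interval, and the adjusted R-squared.
#'
#' @param pairs data frame with columns `peak` (N) and `cov` (%).
#' @return An object of class `regression_result`.
#' @export
regress_peak_vs_cov <- function(pairs) {
  if (!all(c("peak", "cov") %in% names(pairs))) {
    stop_invalid("`pairs` needs columns `peak` and `cov`")
  }
  if (nrow(pairs) < 3L) stop_invalid("need at least 3 pairs")
  if (stats::sd(pairs$peak) == 0) stop_invalid("zero variance in `peak`")
  fit <- stats::lm(cov ~ peak, data = pairs)
  ci <- stats::confint(fit, "peak", level = 0.95)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    slope_ci = c(lower = ci[1], upper = ci[2]),
    adj_r_squared = summary(fit)$adj.r.squared,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("COV = %.3f %+.4f x peak  (slope 95%% CI [%.4f, %.4f], adj R2 = %.3f)\n",
              x$intercept, x$slope, x$slope_ci[1], x$slope_ci[2],
              x$adj_r_squared))
  invisible(x)
}
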