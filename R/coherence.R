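# Intermuscular coherence chain: Hilbert-envelope preprocessing, segment-
# averaged auto/cross spectra, squared coherence with analytic confidence
# limits, segment-weighted pooling across records, and chi-squared tests for
# within-group heterogeneity and between-group differences on the
# variance-stabilized (inverse hyperbolic tangent) scale.

COHERENCE_BANDS <- list(alpha = c(8, 16), beta = c(16, 30), gamma = c(30, 60))

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones, inverse-transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Envelope preprocessing for coherence analysis
#'
#' Clips the steadiest window out of a raw EMG channel, high-pass filters it
#' (zero-phase Butterworth), normalizes to unit variance, and rectifies and
#' envelopes it in one operation as the magnitude of the analytic signal.
#'
#' @param emg numeric raw EMG series (one channel, full trial).
#' @param window a `steady_window` locating the analysis period (fields
#'   `start`, `width` in seconds).
#' @param fs sampling rate of `emg`, Hz.
#' @param hp_hz high-pass corner frequency, Hz.
#' @param order Butterworth order (applied forward-backward).
#' @return An object of class `preprocessed_envelope` with unit-variance-
#'   normalized envelope `samples` and `fs`.
#' @export
preprocess_envelope <- function(emg, window, fs, hp_hz = 20, order = 4) {
  i0 <- round_half_up(window$start * fs) + 1
  len <- round_half_up(window$width * fs)
  if (i0 < 1 || i0 + len - 1 > length(emg)) {
    stop_invalid("window lies outside the EMG series")
  }
  x <- emg[i0:(i0 + len - 1)]
  if (stats::sd(x) == 0) stop_invalid("zero-variance EMG input")
  hp <- signal::butter(order, hp_hz / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, x)
  x <- (x - mean(x)) / stats::sd(x)
  env <- Mod(analytic_signal(x))
  structure(list(samples = env, fs = fs, window = window),
            class = "preprocessed_envelope")
}

#' Segment-averaged auto- and cross-spectra
#'
#' Splits the two series into non-overlapping segments of `segment_s`
#' seconds (in samples: `floor(segment_s * fs)`), removes each segment's
#' mean, applies a plain (rectangular-window) discrete Fourier transform,
#' and averages periodograms across segments. A 4 s window with 460 ms
#' segments yields L = 8 segments and a frequency resolution of about
#' 2.17 Hz.
#'
#' @param x,y `preprocessed_envelope` objects (or numeric series) of equal
#'   length and sampling rate.
#' @param segment_s segment duration, seconds.
#' @param fs sampling rate, required only when `x` and `y` are bare numeric
#'   series.
#' @return An object of class `spectral_estimate` with `freqs`, real
#'   auto-spectra `f_xx`, `f_yy`, complex cross-spectrum `f_xy`, and the
#'   segment count `L`.
#' @export
estimate_spectra <- function(x, y, segment_s = 0.46, fs = NULL) {
  if (inherits(x, "preprocessed_envelope")) { fs <- x$fs; x <- x$samples }
  if (inherits(y, "preprocessed_envelope")) { y <- y$samples }
  if (is.null(fs)) stop_invalid("`fs` required for bare numeric input")
  if (length(x) != length(y)) stop_invalid("`x` and `y` lengths differ")
  seg <- as.integer(floor(segment_s * fs))
  L <- length(x) %/% seg
  if (L < 1L) stop_invalid("fewer than one full segment of data")
  nf <- seg %/% 2 + 1L
  f_xx <- f_yy <- numeric(nf)
  f_xy <- complex(nf)
  for (l in seq_len(L)) {
    idx <- ((l - 1L) * seg + 1L):(l * seg)
    X <- stats::fft(x[idx] - mean(x[idx]))[seq_len(nf)]
    Y <- stats::fft(y[idx] - mean(y[idx]))[seq_len(nf)]
    f_xx <- f_xx + Mod(X)^2
    f_yy <- f_yy + Mod(Y)^2
    f_xy <- f_xy + X * Conj(Y)
  }
  norm <- 1 / (2 * pi * seg * L)
  structure(list(freqs = (seq_len(nf) - 1) * fs / seg,
                 f_xx = f_xx * norm, f_yy = f_yy * norm, f_xy = f_xy * norm,
                 L = L, fs = fs, segment_samples = seg),
            class = "spectral_estimate")
}

#' Analytic 95% confidence limit for coherence
#'
#' The per-frequency value above which squared coherence estimated from `L`
#' independent segments is significant at the 5% level:
#' `CL = 1 - 0.05^(1/(L - 1))`.
#'
#' @param L segment count, >= 2.
#' @return the confidence limit, in (0, 1).
#' @export
confidence_limit <- function(L) {
  if (any(L < 2)) stop_invalid("`L` must be >= 2")
  1 - 0.05^(1 / (L - 1))
}

#' Squared coherence from a spectral estimate
#'
#' `|R(f)|^2 = |f_xy|^2 / (f_xx * f_yy)` per frequency bin, with the
#' analytic confidence limit attached. Bins with a zero auto-spectrum get
#' coherence 0 with a warning.
#'
#' @param spec a [estimate_spectra()] result with `L >= 2`.
#' @return An object of class `coherence_spectrum` with `freqs`, `R2`, `L`
#'   and `CL`.
#' @export
coherence <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (spec$L < 2L) stop_invalid("need at least 2 segments")
  denom <- spec$f_xx * spec$f_yy
  R2 <- numeric(length(denom))
  ok <- denom > 0
  if (!all(ok)) warning("zero auto-spectrum bin(s); coherence set to 0",
                        call. = FALSE)
  R2[ok] <- Mod(spec$f_xy[ok])^2 / denom[ok]
  R2 <- pmin(1, pmax(0, R2))
  structure(list(freqs = spec$freqs, R2 = R2, L = spec$L,
                 CL = confidence_limit(spec$L)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("Coherence spectrum: %d bins (%.2f Hz resolution), L = %d, CL = %.3f\n",
              length(x$freqs), diff(x$freqs[1:2]), x$L, x$CL))
  invisible(x)
}

check_same_grid <- function(specs) {
  f0 <- specs[[1]]$freqs
  same <- vapply(specs, function(s) {
    length(s$freqs) == length(f0) && all(abs(s$freqs - f0) < 1e-9)
  }, logical(1))
  if (!all(same)) stop_invalid("mismatched frequency grids")
  f0
}

#' Segment-weighted pooled coherence across records
#'
#' Pools the auto- and cross-spectra of several records by segment-count-
#' weighted summation, and evaluates squared coherence on the pooled spectra.
#' The confidence limit uses the total segment count. When two or more
#' records are supplied, per-bin within-group heterogeneity (chi-squared on
#' the variance-stabilized scale) is attached.
#'
#' @param specs list of [estimate_spectra()] results on identical frequency
#'   grids.
#' @return An object of class `pooled_coherence` with `freqs`, pooled `R2`,
#'   total `L`, `CL`, per-bin `significant` flags and (when available) a
#'   `heterogeneity` table.
#' @export
pool_coherence <- function(specs) {
  if (inherits(specs, "spectral_estimate")) specs <- list(specs)
  freqs <- check_same_grid(specs)
  Ls <- vapply(specs, function(s) as.integer(s$L), integer(1))
  f_xx <- Reduce(`+`, Map(function(s) s$L * s$f_xx, specs))
  f_yy <- Reduce(`+`, Map(function(s) s$L * s$f_yy, specs))
  f_xy <- Reduce(`+`, Map(function(s) s$L * s$f_xy, specs))
  denom <- f_xx * f_yy
  R2 <- numeric(length(denom))
  ok <- denom > 0
  R2[ok] <- Mod(f_xy[ok])^2 / denom[ok]
  R2 <- pmin(1, pmax(0, R2))
  Ltot <- sum(Ls)
  CL <- confidence_limit(Ltot)
  het <- if (length(specs) >= 2L) within_group_heterogeneity(specs) else NULL
  structure(list(freqs = freqs, R2 = R2, L = Ltot, CL = CL,
                 significant = R2 > CL, n_records = length(specs),
                 heterogeneity = het),
            class = "pooled_coherence")
}

#' @export
print.pooled_coherence <- function(x, ...) {
  cat(sprintf("Pooled coherence: %d records, %d segments, CL = %.4f, %d significant bins\n",
              x$n_records, x$L, x$CL, sum(x$significant)))
  invisible(x)
}

#' Within-group heterogeneity of coherence (chi-squared)
#'
#' Per frequency bin, each record's coherence magnitude is variance-
#' stabilized as `z_i = atanh(|R_i|)` (variance about `1/(2 L_i)`); the
#' statistic `sum(2 L_i (z_i - weighted mean)^2)` is compared to a
#' chi-squared distribution with k - 1 degrees of freedom. Flags mark bins
#' where the records disagree at the 5% level.
#'
#' @param specs list of at least two [estimate_spectra()] results (or
#'   `coherence_spectrum` objects) on identical grids.
#' @return data frame with columns `freq`, `chi2`, `df`, `p`, `flag`.
#' @export
within_group_heterogeneity <- function(specs) {
  if (length(specs) < 2L) stop_invalid("need at least 2 records")
  cohs <- lapply(specs, function(s) {
    if (inherits(s, "spectral_estimate")) coherence(s) else s
  })
  freqs <- check_same_grid(cohs)
  Ls <- vapply(cohs, `[[`, numeric(1), "L")
  zmat <- vapply(cohs, function(co) {
    atanh(pmin(sqrt(co$R2), 1 - 1e-12))
  }, numeric(length(freqs)))
  w <- 2 * Ls
  zbar <- as.vector(zmat %*% w) / sum(w)
  chi2 <- as.vector((zmat - zbar)^2 %*% w)
  df <- length(cohs) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  data.frame(freq = freqs, chi2 = chi2, df = df, p = p, flag = p < 0.05)
}

#' Between-group difference of pooled coherence
#'
#' The per-bin difference of variance-stabilized pooled coherence magnitudes,
#' `atanh(|R_a|) - atanh(|R_b|)`, with 95% limits
#' `+/- 1.96 * sqrt(1/(2 L_a) + 1/(2 L_b))`. Bins outside the limits are
#' flagged with the direction of the difference. Swapping the groups negates
#' the statistic.
#'
#' @param a,b [pool_coherence()] results on the same grid.
#' @return An object of class `coherence_diff` with `freqs`, `statistic`,
#'   `ci_half_width`, and per-bin `direction` (`"a>b"`, `"b>a"` or `"ns"`).
#' @export
between_group_difference <- function(a, b) {
  freqs <- check_same_grid(list(a, b))
  za <- atanh(pmin(sqrt(a$R2), 1 - 1e-12))
  zb <- atanh(pmin(sqrt(b$R2), 1 - 1e-12))
  stat <- za - zb
  hw <- 1.96 * sqrt(1 / (2 * a$L) + 1 / (2 * b$L))
  dir <- rep("ns", length(stat))
  dir[stat > hw] <- "a>b"
  dir[stat < -hw] <- "b>a"
  structure(list(freqs = freqs, statistic = stat, ci_half_width = hw,
                 direction = dir),
            class = "coherence_diff")
}

#' @export
print.coherence_diff <- function(x, ...) {
  cat(sprintf("Coherence difference: %d bins, CI half-width %.3f, %d flagged\n",
              length(x$freqs), x$ci_half_width, sum(x$direction != "ns")))
  invisible(x)
}

#' Percentage of individual trials with significant coherence per bin
#'
#' Each trial is assessed against its own confidence limit (from its own
#' segment count).
#'
#' @param cohs list of `coherence_spectrum` objects on identical grids.
#' @return data frame with columns `freq` and `pct_significant` in
#'   `[0, 100]`.
#' @export
percent_significant_trials <- function(cohs) {
  freqs <- check_same_grid(cohs)
  sig <- vapply(cohs, function(co) co$R2 > co$CL, logical(length(freqs)))
  data.frame(freq = freqs,
             pct_significant = 100 * rowMeans(sig))
}

#' Band-averaged pooled coherence
#'
#' Mean pooled squared coherence over the alpha (8-16 Hz), beta (16-30 Hz)
#' and gamma (30-60 Hz) bands. Bands are half-open `[lo, hi)` so each bin
#' belongs to exactly one band. A band not covered by the frequency grid is
#' omitted with a warning.
#'
#' @param pooled a [pool_coherence()] (or `coherence_spectrum`) result.
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @return data frame with columns `band`, `lo`, `hi`, `mean_coherence`.
#' @export
band_average <- function(pooled, bands = COHERENCE_BANDS) {
  out <- lapply(names(bands), function(b) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    if (max(pooled$freqs) < hi || min(pooled$freqs) > lo) {
      warning("frequency grid does not cover the ", b, " band; omitted",
              call. = FALSE)
      return(NULL)
    }
    sel <- pooled$freqs >= lo & pooled$freqs < hi
    data.frame(band = b, lo = lo, hi = hi,
               mean_coherence = mean(pooled$R2[sel]))
  })
  do.call(rbind, out)
}

#' Crosstalk quality-control flag
#'
#' Uniformly high coherence across every analysis band is the signature of
#' electrode crosstalk rather than shared neural drive. The flag is raised
#' when squared coherence exceeds `threshold` at every bin of every band
#' simultaneously.
#'
#' @param coh a `coherence_spectrum` (or `pooled_coherence`) object.
#' @param threshold coherence level indicating crosstalk.
#' @param bands named list of band edges, Hz.
#' @return logical flag.
#' @export
crosstalk_qc <- function(coh, threshold = 0.8, bands = COHERENCE_BANDS) {
  all(vapply(bands, function(bd) {
    sel <- coh$freqs >= bd[1] & coh$freqs < bd[2]
    length(sel) > 0 && all(coh$R2[sel] > threshold)
  }, logical(1)))
}
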