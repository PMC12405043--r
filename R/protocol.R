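#' Trapezoidal pinch-trial protocol description
#'
#' Defines the submaximal trapezoidal contraction protocol: a ramp up to the
#' target force, a steady isometric hold, and a ramp back to rest, repeated at
#' several target levels expressed as fractions of the maximal voluntary
#' contraction (MVC). Defaults follow a 2 s ramp, 10 s hold, targets at 15,
#' 35, 55 and 70% MVC with three repeats per level, EMG sampled at 2222 Hz
#' with a 20-450 Hz bandwidth, and force sampled at 1000 Hz. A short
#' pre-ramp baseline and post-release rest are recorded around the trapezoid
#' so that ramp-phase analyses over the first 15 s of a trial are defined.
#'
#' @param force_levels numeric vector of target levels, fractions of MVC in
#'   (0, 1].
#' @param ramp_s ramp duration in seconds (both up and down).
#' @param hold_s steady hold duration in seconds.
#' @param repeats_per_level number of trials per target level.
#' @param emg_fs EMG sampling rate in Hz.
#' @param force_fs force sampling rate in Hz.
#' @param emg_band EMG hardware bandwidth, c(low, high) in Hz.
#' @param pre_s quiet baseline recorded before the ramp, seconds.
#' @param post_s rest recorded after the down-ramp, seconds.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(force_levels = c(0.15, 0.35, 0.55, 0.70),
                          ramp_s = 2, hold_s = 10, repeats_per_level = 3,
                          emg_fs = 2222, force_fs = 1000,
                          emg_band = c(20, 450),
                          pre_s = 0.5, post_s = 1.5) {
  if (!is.numeric(force_levels) || length(force_levels) < 1L ||
      any(force_levels <= 0 | force_levels > 1)) {
    stop_invalid("`force_levels` must be fractions of MVC in (0, 1]")
  }
  if (!is_scalar_num(ramp_s) || ramp_s <= 0) stop_invalid("`ramp_s` must be > 0")
  if (!is_scalar_num(hold_s) || hold_s <= 0) stop_invalid("`hold_s` must be > 0")
  if (!is_scalar_num(repeats_per_level) || repeats_per_level < 1) {
    stop_invalid("`repeats_per_level` must be >= 1")
  }
  if (length(emg_band) != 2L || emg_band[1] <= 0 || emg_band[2] <= emg_band[1]) {
    stop_invalid("`emg_band` must be c(low, high) with 0 < low < high")
  }
  if (emg_fs <= 2 * emg_band[2]) {
    stop_invalid("`emg_fs` must exceed twice the upper EMG band edge")
  }
  structure(list(
    force_levels = as.numeric(force_levels),
    ramp_s = ramp_s, hold_s = hold_s,
    repeats_per_level = as.integer(repeats_per_level),
    emg_fs = emg_fs, force_fs = force_fs,
    emg_band = as.numeric(emg_band),
    pre_s = pre_s, post_s = post_s
  ), class = "protocol_spec")
}

#' Total duration of one trial under a protocol
#' @param protocol a [protocol_spec()].
#' @return duration in seconds (baseline + ramp + hold + down-ramp + rest).
#' @export
trial_duration <- function(protocol) {
  with(protocol, pre_s + ramp_s + hold_s + ramp_s + post_s)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Trapezoidal pinch protocol\n")
  cat(sprintf("  levels: %s %% MVC, %d repeats each\n",
              paste(round(100 * x$force_levels), collapse = "/"),
              x$repeats_per_level))
  cat(sprintf("  ramp %g s, hold %g s (total trial %g s)\n",
              x$ramp_s, x$hold_s, trial_duration(x)))
  cat(sprintf("  EMG %g Hz (%g-%g Hz band), force %g Hz\n",
              x$emg_fs, x$emg_band[1], x$emg_band[2], x$force_fs))
  invisible(x)
}

#' Common oscillatory drive specification
#'
#' Describes the band-limited synaptic noise injected into both muscles' motor
#' neuron pools. A fraction `strength` of the oscillatory drive variance is
#' shared between the two pools (one realization added to both), the rest is
#' independent per pool; intermuscular coherence at the drive band arises only
#' from the shared part. A slow (< 5 Hz) independent component emulates the
#' low-frequency drive variability that produces force unsteadiness.
#'
#' @param band_center center of the oscillatory band, Hz (within 0-110 Hz).
#' @param band_width full width of the band, Hz.
#' @param strength fraction in [0, 1] of oscillatory drive variance shared
#'   across the two pools.
#' @param noise_sd standard deviation of the oscillatory drive, in units of
#'   fractional MVC excitation.
#' @param slow_sd standard deviation of the slow (< 5 Hz) independent drive
#'   component, fractional MVC.
#' @return An object of class `common_drive_spec`.
#' @export
common_drive_spec <- function(band_center = 21, band_width = 6,
                              strength = 0, noise_sd = 0.012,
                              slow_sd = 0.006) {
  if (!is_scalar_num(strength) || strength < 0 || strength > 1) {
    stop_invalid("`strength` must be in [0, 1]")
  }
  lo <- band_center - band_width / 2
  hi <- band_center + band_width / 2
  if (lo <= 0 || hi > 110) stop_invalid("drive band must lie within 0-110 Hz")
  structure(list(band_center = band_center, band_width = band_width,
                 strength = strength, noise_sd = noise_sd, slow_sd = slow_sd),
            class = "common_drive_spec")
}

#' @export
print.common_drive_spec <- function(x, ...) {
  cat(sprintf(
    "Common drive: %g Hz band (width %g Hz), shared fraction %g, sd %g\n",
    x$band_center, x$band_width, x$strength, x$noise_sd))
  invisible(x)
}
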