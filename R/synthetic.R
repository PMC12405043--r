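# Synthetic motor-neuron-pool cohort generator.
#
# A rate-coded pool drives both force (twitch-convolved spike trains, with a
# static calibration so steady-state force is linear in excitation) and
# surface EMG (MUAP-convolved spike trains mixed into four channels per
# muscle). Common band-limited synaptic noise injected into both pools is the
# physiologic origin of intermuscular coherence in the generated data.

MUSCLES <- c("APB", "FDS")

#' Generate a rate-coded motor-unit pool
#'
#' Recruitment thresholds follow an exponential spacing over `[0, thr_max]`
#' (many low-threshold units, few high-threshold ones), the classic
#' size-principle arrangement. Twitch amplitude grows exponentially with
#' threshold rank; twitch contraction time shrinks with size; the motor-unit
#' action potential (MUAP) used for EMG synthesis grows in amplitude and
#' duration with unit size.
#'
#' @param n_units number of motor units (>= 1).
#' @param mvc_scale force, in newtons, that the pool's muscle contributes at
#'   full excitation (its share of the pinch MVC).
#' @param seed integer seed; fixed seed gives an identical pool.
#' @param thr_max highest recruitment threshold, fraction of MVC; above it
#'   force is graded by rate coding alone.
#' @param range_twitch ratio of largest to smallest twitch amplitude.
#' @param min_rate,peak_rate firing-rate floor and ceiling, Hz. Following
#'   the onion-skin organization, the effective ceiling decreases with
#'   recruitment threshold by `onion_skin` Hz across the pool.
#' @param onion_skin drop in peak rate from the lowest- to the highest-
#'   threshold unit, Hz.
#' @param rate_gain firing-rate increase per unit of excess excitation,
#'   Hz per fractional MVC.
#' @param isi_cv coefficient of variation of inter-spike-interval jitter
#'   (dimensionless, in [0, 0.3]).
#' @param hysteresis recruitment hysteresis, fractional MVC: once recruited,
#'   a unit keeps firing until excitation falls this far below its threshold
#'   (a persistent-inward-current-like property of real motor neurons).
#' @return A data frame of class `mu_pool`, one row per unit, ordered by
#'   strictly increasing recruitment threshold.
#' @export
generate_pool <- function(n_units, mvc_scale = 60, seed = 1L,
                          thr_max = 0.65, range_twitch = 30,
                          min_rate = 12, peak_rate = 30, rate_gain = 100,
                          onion_skin = 8, isi_cv = 0.15, hysteresis = 0.02) {
  if (!is_scalar_num(n_units) || n_units < 1) {
    stop_invalid("`n_units` must be >= 1")
  }
  if (isi_cv < 0 || isi_cv > 0.3) stop_invalid("`isi_cv` must be in [0, 0.3]")
  if (min_rate >= peak_rate) stop_invalid("`min_rate` must be < `peak_rate`")
  n_units <- as.integer(n_units)
  i <- seq_len(n_units)
  # exponential threshold spacing: t_1 = 0, t_n = thr_max
  if (n_units == 1L) {
    thr <- 0
  } else {
    a <- log(range_twitch)
    thr <- thr_max * (exp(a * (i - 1) / (n_units - 1)) - 1) / (exp(a) - 1)
  }
  twitch_amp <- exp(log(range_twitch) * thr / thr_max)
  # hand-muscle contraction times: 70 ms for the smallest unit down to 30 ms
  twitch_ct <- 0.070 - 0.040 * thr / thr_max
  pool <- with_seed(seed, {
    data.frame(
      unit = i,
      threshold = thr,
      min_rate = min_rate,
      peak_rate = peak_rate - onion_skin * thr / max(thr_max, 1e-9),
      rate_gain = rate_gain,
      isi_cv = isi_cv,
      hysteresis = hysteresis,
      twitch_amp = twitch_amp,
      twitch_ct = twitch_ct,
      # surface MUAP: amplitude sub-linear in twitch size, duration 5-15 ms
      muap_amp = twitch_amp^0.6 * exp(stats::rnorm(n_units, 0, 0.1)),
      muap_dur = (0.005 + 0.010 * thr / thr_max) *
        exp(stats::rnorm(n_units, 0, 0.05))
    )
  })
  structure(pool, class = c("mu_pool", "data.frame"),
            mvc_scale = mvc_scale, seed = seed)
}

#' @export
print.mu_pool <- function(x, ...) {
  cat(sprintf("Motor-unit pool: %d units, thresholds %.3f-%.3f MVC, %g N at full drive\n",
              nrow(x), min(x$threshold), max(x$threshold), attr(x, "mvc_scale")))
  invisible(x)
}

# Instantaneous firing rate of every unit at excitation level `d`.
pool_rates <- function(pool, d) {
  r <- pool$min_rate + pool$rate_gain * (d - pool$threshold)
  r[d < pool$threshold] <- 0
  pmin(r, pool$peak_rate)
}

# Expected static (unconvolved, twitch-area weighted) force of a pool over a
# grid of excitation levels, plus a small passive-elastic term that keeps the
# curve strictly increasing through rate-saturated stretches. Used to
# calibrate the simulated dynamometer so that steady-state calibrated force
# is linear in excitation.
pool_force_curve <- function(pool, grid = seq(0, 1, by = 0.005)) {
  area <- pool$twitch_amp * exp(1) * pool$twitch_ct  # integral of the twitch kernel
  raw <- vapply(grid, function(d) sum(area * pool_rates(pool, d)), numeric(1))
  raw <- raw + 0.01 * max(raw) * grid
  list(grid = grid, raw = raw)
}

# Second-order critically damped twitch kernel, peak 1 at t = ct.
twitch_kernel <- function(ct, fs) {
  t <- seq(0, 5 * ct, by = 1 / fs)
  (t / ct) * exp(1 - t / ct)
}

# Biphasic (Hermite-like, derivative-of-Gaussian) MUAP kernel with the given
# support, peak amplitude 1.
muap_kernel <- function(dur, fs) {
  n <- max(5L, as.integer(round(dur * fs)))
  t <- seq(-3, 3, length.out = n)
  k <- -t * exp(-t^2 / 2)
  k / max(abs(k))
}

# Zero-phase filtering by squared-magnitude Butterworth response applied in
# the frequency domain (equivalent to forward-backward filtering up to edge
# treatment; circular edges are immaterial for the padded synthetic trials).
fft_zero_phase <- function(x, filt) {
  n <- length(x)
  z <- exp(-2i * pi * (seq_len(n) - 1) / n)
  num <- 0; den <- 0; zp <- rep(1 + 0i, n)
  nb <- max(length(filt$b), length(filt$a))
  b <- c(filt$b, numeric(nb - length(filt$b)))
  a <- c(filt$a, numeric(nb - length(filt$a)))
  for (k in seq_len(nb)) {
    num <- num + b[k] * zp
    den <- den + a[k] * zp
    zp <- zp * z
  }
  H2 <- Mod(num / den)^2
  Re(stats::fft(stats::fft(x) * H2, inverse = TRUE)) / n
}

# Band-limited Gaussian noise (Butterworth-shaped white noise), scaled to the
# requested standard deviation.
bandlimited_noise <- function(n, fs, band, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  w <- band / (fs / 2)
  filt <- if (is.na(w[1]) || w[1] <= 0) {
    signal::butter(2, w[2], type = "low")
  } else {
    signal::butter(2, w, type = "pass")
  }
  y <- fft_zero_phase(x, filt)
  y * sd_target / stats::sd(y)
}

# Event-driven spike generation for one unit given the excitation series `d`
# sampled at `fs`. First spike at the first threshold crossing; subsequent
# intervals 1/rate with multiplicative Gaussian jitter of CV `isi_cv`. Once
# recruited, the unit keeps firing until excitation drops `hysteresis` below
# its threshold (recruitment hysteresis), then waits for the next crossing.
simulate_unit_spikes <- function(d, fs, threshold, min_rate, peak_rate,
                                 rate_gain, isi_cv, hysteresis = 0) {
  n <- length(d)
  active <- which(d >= threshold)
  if (length(active) == 0L) return(numeric(0))
  off_level <- threshold - hysteresis
  t_end <- (n - 1) / fs
  spikes <- numeric(0)
  t <- (active[1] - 1) / fs
  repeat {
    spikes <- c(spikes, t)
    i <- min(n, floor(t * fs) + 1)
    r <- min(peak_rate, min_rate + rate_gain * (d[i] - threshold))
    r <- max(r, min_rate)
    jit <- if (isi_cv > 0) max(0.05, 1 + isi_cv * stats::rnorm(1)) else 1
    t_next <- t + jit / r
    if (t_next > t_end) break
    j <- floor(t_next * fs) + 1
    if (d[j] >= off_level) {
      t <- t_next
    } else {
      pos <- findInterval(j, active)
      if (pos >= length(active)) break
      t <- (active[pos + 1] - 1) / fs
    }
  }
  spikes
}

# Sum `kernel` into a length-`n` signal at the given sample indices.
add_impulses <- function(n, idx, kernel) {
  out <- numeric(n + length(kernel))
  for (k in seq_along(kernel)) {
    at <- idx + k - 1L
    out[at] <- out[at] + kernel[k]
  }
  out[seq_len(n)]
}

# Trapezoid excitation profile in fractional-MVC units on a time grid.
trapezoid_profile <- function(tt, protocol, level) {
  p <- protocol
  t1 <- p$pre_s; t2 <- t1 + p$ramp_s; t3 <- t2 + p$hold_s; t4 <- t3 + p$ramp_s
  out <- numeric(length(tt))
  up <- tt >= t1 & tt < t2
  out[up] <- level * (tt[up] - t1) / p$ramp_s
  out[tt >= t2 & tt < t3] <- level
  dn <- tt >= t3 & tt < t4
  out[dn] <- level * (1 - (tt[dn] - t3) / p$ramp_s)
  out
}

#' Simulate one trapezoidal pinch trial
#'
#' Both muscles' pools receive the trapezoid excitation plus band-limited
#' oscillatory noise (a fraction `drive$strength` of whose variance is one
#' shared realization) plus independent slow noise. Units fire when excitation
#' exceeds their recruitment threshold, at a rate linear in the excess, with
#' multiplicative inter-spike-interval jitter. Force is the calibrated sum of
#' twitch-convolved spike trains plus measurement noise; each EMG channel is a
#' mixed sum of MUAP-convolved spike trains plus white noise, band-limited to
#' the protocol's EMG bandwidth.
#'
#' @param pool_pair named list of two [generate_pool()] pools, names
#'   `c("APB", "FDS")`.
#' @param drive a [common_drive_spec()].
#' @param protocol a [protocol_spec()].
#' @param level target force as a fraction of MVC; must be one of
#'   `protocol$force_levels`.
#' @param seed integer seed; the trial is fully reproducible from it.
#' @param emg_snr_db EMG signal-to-noise ratio in dB during the contraction.
#' @param n_channels EMG channels synthesized per muscle.
#' @return An object of class `synthetic_trial`: the force trace (a
#'   [force_trace()]), per-muscle EMG channel matrices, per-muscle lists of
#'   [spike_train()]s with ground-truth recruitment thresholds, and metadata.
#' @export
simulate_trial <- function(pool_pair, drive, protocol, level, seed = 1L,
                           emg_snr_db = 15, n_channels = 4L) {
  if (!is_scalar_num(level) || level <= 0 || level > 1) {
    stop_invalid("`level` must be a fraction of MVC in (0, 1]")
  }
  if (!all(MUSCLES %in% names(pool_pair))) {
    stop_invalid("`pool_pair` must be a named list with elements APB and FDS")
  }
  dur <- trial_duration(protocol)
  ffs <- protocol$force_fs
  efs <- protocol$emg_fs
  nf <- as.integer(round(dur * ffs))
  ne <- as.integer(round(dur * efs))
  tf <- (seq_len(nf) - 1) / ffs
  base <- trapezoid_profile(tf, protocol, level)
  band <- drive$band_center + c(-0.5, 0.5) * drive$band_width
  mvc <- sum(vapply(pool_pair, attr, numeric(1), "mvc_scale"))

  with_seed(seed, {
    shared <- bandlimited_noise(nf, ffs, band,
                                sqrt(drive$strength) * drive$noise_sd)
    spikes <- list()
    force_cal <- numeric(nf)
    emg <- list()
    for (m in MUSCLES) {
      pool <- pool_pair[[m]]
      indep <- bandlimited_noise(nf, ffs, band,
                                 sqrt(1 - drive$strength) * drive$noise_sd)
      slow <- bandlimited_noise(nf, ffs, c(NA, 5), drive$slow_sd)
      d <- pmax(0, base + shared + indep + slow)
      sp <- lapply(seq_len(nrow(pool)), function(u) {
        simulate_unit_spikes(d, ffs, pool$threshold[u], pool$min_rate[u],
                             pool$peak_rate[u], pool$rate_gain[u],
                             pool$isi_cv[u], pool$hysteresis[u])
      })
      # force: twitch-convolved spike trains plus the passive-elastic term,
      # then the static linearizing calibration
      raw <- numeric(nf)
      for (u in seq_len(nrow(pool))) {
        if (length(sp[[u]]) == 0L) next
        idx <- pmin(nf, floor(sp[[u]] * ffs) + 1L)
        kern <- pool$twitch_amp[u] * twitch_kernel(pool$twitch_ct[u], ffs)
        raw <- raw + add_impulses(nf, idx, kern)
      }
      curve <- pool_force_curve(pool)
      raw <- raw + 0.01 * max(curve$raw) / 1.01 * d
      cal <- stats::approx(x = curve$raw, y = curve$grid, xout = raw,
                           rule = 2)$y
      force_cal <- force_cal + attr(pool, "mvc_scale") * cal

      # EMG: per-unit MUAP trains mixed into channels
      unit_sig <- matrix(0, ne, nrow(pool))
      for (u in seq_len(nrow(pool))) {
        if (length(sp[[u]]) == 0L) next
        idx <- pmin(ne, floor(sp[[u]] * efs) + 1L)
        kern <- pool$muap_amp[u] * muap_kernel(pool$muap_dur[u], efs)
        unit_sig[, u] <- add_impulses(ne, idx, kern)
      }
      gains <- cbind(1, matrix(stats::runif(nrow(pool) * (n_channels - 1L),
                                            0.5, 0.9), nrow(pool)))
      clean <- unit_sig %*% gains
      sd_ref <- stats::sd(clean[, 1])
      noise_sd <- if (sd_ref > 0) sd_ref / 10^(emg_snr_db / 20) else 1e-3
      noisy <- clean + matrix(stats::rnorm(ne * n_channels, 0, noise_sd), ne)
      bp <- signal::butter(4, protocol$emg_band / (efs / 2), type = "pass")
      emg[[m]] <- apply(noisy, 2, function(ch) fft_zero_phase(ch, bp))
      colnames(emg[[m]]) <- paste0("ch", seq_len(n_channels))

      spikes[[m]] <- lapply(seq_len(nrow(pool)), function(u) {
        spike_train(sp[[u]], unit_id = sprintf("%s_%02d", m, u), muscle = m,
                    accuracy = min(100, max(70, stats::rnorm(1, 94, 3))),
                    true_threshold = pool$threshold[u])
      })
      spikes[[m]] <- Filter(function(s) length(s$times) > 0, spikes[[m]])
    }
    force_cal <- force_cal + stats::rnorm(nf, 0, 0.002 * mvc)
    force <- force_trace(force_cal, fs = ffs, target = level * mvc,
                         level = level, ramp_s = protocol$ramp_s,
                         hold_s = protocol$hold_s, pre_s = protocol$pre_s)
    structure(list(
      level = level, mvc = mvc, force = force,
      target_profile = mvc * base,
      emg = emg, emg_fs = efs,
      spikes = spikes, seed = seed, protocol = protocol
    ), class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic pinch trial: %g%% MVC (%.1f N target), %.1f s\n",
              100 * x$level, x$level * x$mvc, trial_duration(x$protocol)))
  cat(sprintf("  EMG: %s channels at %g Hz; spike trains: APB %d, FDS %d\n",
              paste(vapply(x$emg, ncol, integer(1)), collapse = "+"),
              x$emg_fs, length(x$spikes$APB), length(x$spikes$FDS)))
  invisible(x)
}

#' Default group presets for a two-group synthetic cohort
#'
#' Illustrative presets emulating a dexterity-trained and a strength-trained
#' group: group mean MVCs follow the two groups' observed means (112.6 and
#' 130.0 N), and both groups receive a beta-band common drive. The presets
#' are study-shaped defaults, not claims about any human dataset.
#'
#' @param strength shared-variance fraction of the oscillatory drive for both
#'   groups.
#' @return named list of per-group specs understood by [generate_cohort()].
#' @export
default_group_specs <- function(strength = 0.3) {
  list(
    dexterity = list(mvc_mean = 112.6, mvc_sd = 12,
                     drive = common_drive_spec(band_center = 21, strength = strength),
                     n_units = 25),
    strength = list(mvc_mean = 130.0, mvc_sd = 12,
                    drive = common_drive_spec(band_center = 21, strength = strength),
                    n_units = 25)
  )
}

#' Generate a synthetic cohort and write trial bundles to disk
#'
#' For each participant, a pair of pools (APB, FDS; the APB contributes 40%
#' of the pinch MVC) is drawn around the group's MVC mean, and one trial is
#' simulated per protocol level and repeat. Trials are written as delimited
#' text bundles (force, EMG, spikes) plus a JSON manifest recording group,
#' participant, level, repeat, file paths and the derived per-trial seed.
#'
#' @param group_specs named list of group presets, see [default_group_specs()].
#' @param protocol a [protocol_spec()].
#' @param n_per_group participants per group (>= 1).
#' @param seed master seed; all per-participant and per-trial seeds derive
#'   from it, so any single trial is reproducible in isolation.
#' @param dir output directory (created if needed). `NULL` keeps the cohort
#'   in memory only.
#' @return Invisibly, the manifest: a data frame with one row per trial and,
#'   as attribute `"trials"`, the in-memory `synthetic_trial` objects.
#' @export
generate_cohort <- function(group_specs = default_group_specs(),
                            protocol = protocol_spec(),
                            n_per_group = 10, seed = 1L, dir = NULL) {
  if (!is_scalar_num(n_per_group) || n_per_group < 1) {
    stop_invalid("`n_per_group` must be >= 1")
  }
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  trials <- list()
  p_idx <- 0L
  for (g in names(group_specs)) {
    gs <- group_specs[[g]]
    for (p in seq_len(n_per_group)) {
      p_idx <- p_idx + 1L
      pid <- sprintf("P%02d", p_idx)
      pseed <- derive_seed(seed, match(g, names(group_specs)), p)
      mvc_p <- with_seed(pseed, max(40, stats::rnorm(1, gs$mvc_mean, gs$mvc_sd)))
      pools <- list(
        APB = generate_pool(gs$n_units, mvc_scale = 0.4 * mvc_p,
                            seed = derive_seed(pseed, 1)),
        FDS = generate_pool(gs$n_units, mvc_scale = 0.6 * mvc_p,
                            seed = derive_seed(pseed, 2))
      )
      for (li in seq_along(protocol$force_levels)) {
        for (r in seq_len(protocol$repeats_per_level)) {
          tseed <- derive_seed(pseed, li, r)
          trial <- simulate_trial(pools, gs$drive, protocol,
                                  protocol$force_levels[li], seed = tseed)
          key <- sprintf("%s_L%02.0f_R%d", pid,
                         100 * protocol$force_levels[li], r)
          paths <- if (!is.null(dir)) {
            write_trial_bundle(trial, dir, key)
          } else {
            list(force = NA, emg = NA, spikes = NA)
          }
          rows[[key]] <- data.frame(
            participant = pid, group = g,
            level = protocol$force_levels[li], rep = r,
            mvc = mvc_p, seed = tseed,
            force_file = paths$force, emg_file = paths$emg,
            spikes_file = paths$spikes,
            stringsAsFactors = FALSE
          )
          trials[[key]] <- trial
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    jsonlite::write_json(
      c(list(seed = seed, n_per_group = n_per_group,
             groups = names(group_specs)),
        list(trials = manifest)),
      file.path(dir, "manifest.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  attr(manifest, "trials") <- trials
  invisible(manifest)
}
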