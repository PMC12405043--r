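# Shared fixtures, generated in code.

# A quick trapezoid force trace with optional additive noise.
make_trace <- function(level = 0.5, mvc = 100, fs = 200, noise_sd = 0,
                       ramp_s = 2, hold_s = 10, pre_s = 0.5, post_s = 1.5,
                       seed = 1) {
  pr <- protocol_spec(force_levels = level, ramp_s = ramp_s, hold_s = hold_s,
                      pre_s = pre_s, post_s = post_s, force_fs = fs)
  tt <- seq(0, pre_s + 2 * ramp_s + hold_s + post_s - 1 / fs, by = 1 / fs)
  base <- mvc * pinchcoh:::trapezoid_profile(tt, pr, level)
  set.seed(seed)
  force_trace(base + rnorm(length(tt), 0, noise_sd), fs = fs,
              target = level * mvc, level = level,
              ramp_s = ramp_s, hold_s = hold_s, pre_s = pre_s)
}

# A periodic spike train covering [t0, t1] at the given rate.
periodic_train <- function(rate, t0 = 0, t1 = 10, ...) {
  spike_train(seq(t0, t1, by = 1 / rate), ...)
}

# A small protocol used by pipeline tests: 2 levels x 1 repeat.
tiny_protocol <- function() {
  protocol_spec(force_levels = c(0.35, 0.70), repeats_per_level = 1)
}

window_at <- function(start, width = 4) {
  structure(list(start = start, width = width, cov = NA_real_),
            class = "steady_window")
}

# Two-template synthetic activity envelopes (force-following vs
# force-inverse), n series per template, Gaussian shape noise.
two_template_envelopes <- function(n_per = 10, len = 150, noise_sd = 0.2,
                                   seed = 1) {
  t <- seq(0, 1, length.out = len)
  up <- pmin(1, pmax(0, (t - 0.1) / 0.2))          # rises and holds
  down <- 1 - up * 0.8 + 0.3 * sin(2 * pi * t)     # roughly inverse shape
  set.seed(seed)
  X <- rbind(
    t(replicate(n_per, up + rnorm(len, 0, noise_sd))),
    t(replicate(n_per, down + rnorm(len, 0, noise_sd)))
  )
  rownames(X) <- paste0("P", seq_len(2 * n_per))
  attr(X, "truth") <- rep(1:2, each = n_per)
  X
}
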