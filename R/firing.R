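# Motor-unit spike-train quality filtering, firing statistics, recruitment
# thresholds, and the mixed-model group comparison of firing rates.

#' Motor-unit spike train
#'
#' @param times spike times in seconds, strictly increasing.
#' @param unit_id unit identifier.
#' @param muscle muscle label (e.g. "APB" or "FDS").
#' @param accuracy decomposition accuracy score in percent, `[0, 100]`.
#' @param true_threshold optional ground-truth recruitment threshold
#'   (fraction of MVC) carried by synthetic trains.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id = "MU1", muscle = "APB",
                        accuracy = 100, true_threshold = NA_real_) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_invalid("spike times must be strictly increasing")
  }
  if (accuracy < 0 || accuracy > 100) {
    stop_invalid("`accuracy` must be in [0, 100]")
  }
  structure(list(times = times, unit_id = unit_id, muscle = muscle,
                 accuracy = accuracy, true_threshold = true_threshold),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train %s (%s): %d spikes, accuracy %.1f%%\n",
              x$unit_id, x$muscle, length(x$times), x$accuracy))
  invisible(x)
}

# Interpulse intervals restricted to spikes inside a steady window.
window_ipis <- function(train, window) {
  t0 <- window$start
  t1 <- window$start + window$width
  inside <- train$times[train$times >= t0 & train$times <= t1]
  diff(inside)
}

#' Quality-filter spike trains inside a steady analysis window
#'
#' A train is retained when its decomposition accuracy is at least
#' `accuracy_min`, it has at least `min_ipis` interpulse intervals (IPIs)
#' inside the window, and the COV of those IPIs does not exceed `max_cov_pct`
#' (trains above it are considered irregularly firing). Trains failing any
#' rule are dropped; an empty result is allowed.
#'
#' @param trains list of [spike_train()]s.
#' @param window a [find_steadiest_window()] result (fields `start`, `width`).
#' @param accuracy_min accuracy gate, percent.
#' @param min_ipis minimum number of in-window IPIs.
#' @param max_cov_pct maximum in-window COV of IPIs, percent.
#' @return the retained subset of `trains`.
#' @export
filter_trains <- function(trains, window, accuracy_min = 90,
                          min_ipis = 7, max_cov_pct = 30) {
  keep <- vapply(trains, function(tr) {
    if (tr$accuracy < accuracy_min) return(FALSE)
    ipis <- window_ipis(tr, window)
    if (length(ipis) < min_ipis) return(FALSE)
    cv <- cv_pct(ipis)
    is.finite(cv) && cv <= max_cov_pct
  }, logical(1))
  trains[keep]
}

#' Mean firing rate inside a steady window
#'
#' The arithmetic mean of reciprocal interpulse intervals, `mean(1 / IPIs)`,
#' over spikes inside the window — not the inverse of the mean interval.
#'
#' @inheritParams filter_trains
#' @param train a [spike_train()].
#' @return mean firing rate in Hz.
#' @export
mean_firing_rate <- function(train, window) {
  ipis <- window_ipis(train, window)
  if (length(ipis) < 1L) stop_invalid("fewer than 1 IPI in the window")
  mean(1 / ipis)
}

#' Recruitment threshold from the onset of regular firing
#'
#' Scans interpulse intervals in order; the first IPI whose first spike is
#' followed by a `win_s`-long period in which the IPIs starting there (at
#' least `min_ipis_in_win` of them) have a COV below `cov_max_pct` marks the
#' onset of regular firing. The force at that onset, linearly interpolated
#' between force samples, is returned as a percentage of MVC.
#'
#' @param train a [spike_train()].
#' @param force a [force_trace()] covering the spike times.
#' @param mvc maximal voluntary contraction, newtons.
#' @param win_s regularity look-ahead window, seconds (default 0.75).
#' @param cov_max_pct regularity criterion on the in-window IPI COV, percent.
#' @param min_ipis_in_win minimum IPIs required inside the look-ahead window
#'   for the COV to be defined.
#' @return threshold in percent of MVC, or `NA` when no IPI qualifies
#'   (no regular onset).
#' @export
firing_threshold <- function(train, force, mvc, win_s = 0.75,
                             cov_max_pct = 30, min_ipis_in_win = 2) {
  stopifnot(inherits(train, "spike_train"), inherits(force, "force_trace"))
  tt <- train$times
  if (length(tt) < 2L) return(NA_real_)
  onsets <- tt[-length(tt)]  # each IPI starts at its first spike
  for (k in seq_along(onsets)) {
    t0 <- onsets[k]
    sel <- onsets >= t0 & onsets < t0 + win_s
    if (sum(sel) < min_ipis_in_win) next
    cv <- cv_pct(diff(tt)[sel])
    if (is.finite(cv) && cv < cov_max_pct) {
      ft <- (seq_along(force$samples) - 1) / force$fs
      f0 <- stats::approx(ft, force$samples, xout = t0, rule = 2)$y
      return(100 * f0 / mvc)
    }
  }
  NA_real_
}

#' Simulate per-motor-unit firing-rate records for parameter recovery
#'
#' Draws a balanced two-group design (levels 15/35/55/70 %MVC, muscles APB
#' and FDS, `n_mu` units per cell) from a Gaussian mixed model with a
#' participant random intercept (SD 1 Hz), a level trend, a threshold slope
#' and residual SD 2 Hz, plus a programmed group effect of `effect_hz` for
#' group "B" in the single (level, muscle) cell named by `cell`. Used to
#' check that [fit_firing_lmm()] recovers programmed contrasts.
#'
#' @param effect_hz group effect injected into the target cell, Hz.
#' @param cell list with `level` (%MVC) and `muscle` naming the target cell.
#' @param n_per_group participants per group.
#' @param n_mu motor units per participant per cell.
#' @param seed integer seed.
#' @return data frame of records accepted by [fit_firing_lmm()].
#' @export
simulate_firing_records <- function(effect_hz = 0,
                                    cell = list(level = 35, muscle = "APB"),
                                    n_per_group = 6, n_mu = 5, seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (g in c("A", "B")) for (p in seq_len(n_per_group)) {
      p_int <- stats::rnorm(1, 0, 1)
      for (lv in c(15, 35, 55, 70)) for (m in c("APB", "FDS")) {
        thr <- stats::runif(n_mu, 0, 0.8 * lv)
        bump <- if (g == "B" && lv == cell$level && m == cell$muscle)
          effect_hz else 0
        rate <- 10 + 0.15 * lv - 0.05 * thr + p_int + bump +
          stats::rnorm(n_mu, 0, 2)
        rows[[length(rows) + 1]] <- data.frame(
          rate = rate, group = g, level = lv, muscle = m,
          participant = paste0(g, p), threshold = thr)
      }
    }
    do.call(rbind, rows)
  })
}

#' Mixed-effects comparison of motor-unit firing rates
#'
#' Fits, by REML, `rate ~ group * level * muscle` with random intercepts for
#' participant and for recruitment threshold (binned into `bin_width_pct`-wide
#' %MVC bins so the continuous threshold forms grouping levels that absorb
#' size-principle variance). Reports Nakagawa marginal/conditional
#' R-squared and estimated-marginal-mean (EMM) group contrasts within each
#' (level, muscle) cell with 95% CIs. Cells with fewer than `min_cell_n`
#' motor units in either group are flagged `small_cell` and should be
#' interpreted cautiously.
#'
#' @param records data frame with columns `rate` (Hz), `group`, `level`
#'   (%MVC, treated as a factor), `muscle`, `participant`, and `threshold`
#'   (% MVC).
#' @param bin_width_pct threshold bin width in %MVC.
#' @param min_cell_n per-group cell size below which contrasts are flagged.
#' @return An object of class `lmm_result`: the fitted model, fixed effects,
#'   marginal and conditional R-squared, EMMs and group contrasts.
#' @export
fit_firing_lmm <- function(records, bin_width_pct = 1, min_cell_n = 3) {
  need <- c("rate", "group", "level", "muscle", "participant", "threshold")
  if (!all(need %in% names(records))) {
    stop_invalid("`records` needs columns ", paste(need, collapse = ", "))
  }
  records$group <- factor(records$group)
  records$level <- factor(records$level)
  records$muscle <- factor(records$muscle)
  if (nlevels(records$level) < 2L) stop_invalid("need at least 2 force levels")
  per_group <- table(records$group, records$participant)
  if (any(rowSums(per_group > 0) < 2L)) {
    stop_invalid("need at least 2 participants per group")
  }
  records$thr_bin <- factor(floor(records$threshold / bin_width_pct))

  form <- if (nlevels(records$muscle) > 1L) {
    rate ~ group * level * muscle + (1 | participant) + (1 | thr_bin)
  } else {
    rate ~ group * level + (1 | participant) + (1 | thr_bin)
  }
  fit <- lme4::lmer(form, data = records, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular fit: a variance component is estimated at 0",
            call. = FALSE)
  }

  # Nakagawa-Schielzeth R2 for a Gaussian LMM with random intercepts
  var_fix <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ran <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  var_res <- attr(lme4::VarCorr(fit), "sc")^2
  r2_marg <- var_fix / (var_fix + var_ran + var_res)
  r2_cond <- (var_fix + var_ran) / (var_fix + var_ran + var_res)

  emm_spec <- if (nlevels(records$muscle) > 1L) {
    emmeans::emmeans(fit, ~ group | level * muscle)
  } else {
    emmeans::emmeans(fit, ~ group | level)
  }
  emm <- as.data.frame(emm_spec)
  contr <- as.data.frame(stats::confint(emmeans::contrast(
    emm_spec, method = "pairwise")))
  # flag small cells
  cell_n <- stats::aggregate(
    rate ~ group + level + muscle, data = records, FUN = length)
  min_n <- stats::aggregate(rate ~ level + muscle, data = cell_n, FUN = min)
  names(min_n)[names(min_n) == "rate"] <- "min_group_n"
  contr <- merge(contr, min_n, by = intersect(c("level", "muscle"),
                                              names(contr)))
  contr$small_cell <- contr$min_group_n < min_cell_n

  structure(list(model = fit, fixed = lme4::fixef(fit),
                 r2_marginal = r2_marg, r2_conditional = r2_cond,
                 emm = emm, contrasts = contr, singular = singular),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Firing-rate mixed model: marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular) " (singular fit)" else ""))
  cat("Group contrasts (EMM differences, 95% CI):\n")
  print(x$contrasts[, setdiff(names(x$contrasts), "min_group_n")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
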