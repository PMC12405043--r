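# Spike-train filtering, firing statistics and the mixed model.

test_that("quality filter applies the three retention rules", {
  win <- window_at(0, 4)
  # 7 spikes = 6 IPIs inside the window: removed
  six_ipi <- spike_train(seq(0.2, 3.8, length.out = 7), accuracy = 99)
  expect_length(filter_trains(list(six_ipi), win), 0)
  # periodic train with 9 spikes (8 IPIs), accuracy 95: kept (COV = 0)
  nine <- spike_train(seq(0.2, 3.4, by = 0.4), accuracy = 95)
  expect_length(filter_trains(list(nine), win), 1)
  # low accuracy alone excludes
  low_acc <- spike_train(seq(0.2, 3.4, by = 0.4), accuracy = 89.9)
  expect_length(filter_trains(list(low_acc), win), 0)
  # irregular firing (COV of IPIs > 30%) excludes
  set.seed(13)
  irr <- spike_train(cumsum(c(0.2, runif(20, 0.02, 0.4))), accuracy = 99)
  expect_length(filter_trains(list(irr), win), 0)
})

test_that("filter matches a brute-force rule check on jittered trains and is
           idempotent", {
  win <- window_at(1, 4)
  set.seed(14)
  trains <- lapply(1:40, function(i) {
    cv <- runif(1, 0, 0.6)
    rate <- runif(1, 5, 20)
    ipis <- pmax(0.01, (1 / rate) * (1 + cv * rnorm(40)))
    spike_train(cumsum(c(runif(1, 0, 1.5), ipis)),
                accuracy = runif(1, 80, 100))
  })
  kept <- filter_trains(trains, win)
  brute <- Filter(function(tr) {
    inside <- tr$times[tr$times >= 1 & tr$times <= 5]
    ipis <- diff(inside)
    tr$accuracy >= 90 && length(ipis) >= 7 &&
      100 * sd(ipis) / mean(ipis) <= 30
  }, trains)
  expect_identical(kept, brute)
  expect_identical(filter_trains(kept, win), kept)
})

test_that("mean firing rate is the mean of reciprocal IPIs", {
  win <- window_at(0, 4)
  per <- spike_train(seq(0.1, 3.9, by = 0.1))
  expect_equal(mean_firing_rate(per, win), 10)
  # IPIs {0.1, 0.2}: mean(10, 5) = 7.5 Hz, not 2 / 0.3
  tr <- spike_train(c(1, 1.1, 1.3))
  expect_equal(mean_firing_rate(tr, win), 7.5)
  # random train equals loop-computed mean of reciprocals
  set.seed(15)
  tt <- cumsum(runif(30, 0.05, 0.3))
  tr2 <- spike_train(tt)
  inside <- tt[tt >= 0 & tt <= 4]
  oracle <- mean(1 / diff(inside))
  expect_equal(mean_firing_rate(tr2, win), oracle)
  expect_error(mean_firing_rate(spike_train(2.5), win), "fewer than 1")
})

test_that("mean firing rate of a periodic train equals its reciprocal
           period exactly", {
  for (p in c(0.05, 0.08, 0.125)) {
    tr <- spike_train(seq(0.2, 3.8, by = p))
    expect_equal(mean_firing_rate(tr, window_at(0, 4)), 1 / p)
  }
})

test_that("firing threshold anchors at the onset of regular firing", {
  # linear ramp force 0 -> 100 N over 10 s, MVC 100 N
  fs <- 500
  ramp <- force_trace(seq(0, 100, length.out = 10 * fs), fs = fs,
                      target = 100, ramp_s = 2, hold_s = 6, pre_s = 0)
  # perfectly periodic train from t0 = 3 s: onset at t0, force(3 s) = 30 N
  per <- spike_train(seq(3, 9, by = 0.1))
  expect_equal(firing_threshold(per, ramp, 100), 30, tolerance = 0.1)
  # single spike: no IPI, sentinel
  expect_true(is.na(firing_threshold(spike_train(3), ramp, 100)))
  # irregular-then-regular: onset skips the irregular prefix
  irr <- spike_train(c(1.0, 1.5, 1.58, 2.6, seq(4, 9, by = 0.1)))
  expect_equal(firing_threshold(irr, ramp, 100), 40, tolerance = 0.2)
  # entirely irregular train: sentinel
  set.seed(16)
  bad <- spike_train(cumsum(runif(12, 0.02, 0.9)))
  expect_true(is.na(firing_threshold(bad, ramp, 100, cov_max_pct = 5)))
})

test_that("thresholds on generated ramps recover construction values within
           1% MVC", {
  fs <- 500
  ramp <- force_trace(seq(0, 100, length.out = 10 * fs), fs = fs,
                      target = 100, ramp_s = 2, hold_s = 6, pre_s = 0)
  for (thr in c(10, 30, 55)) {
    t0 <- thr / 10           # ramp reaches thr% at t = thr/10 s
    tr <- spike_train(seq(t0, 9.5, by = 0.08))
    expect_equal(firing_threshold(tr, ramp, 100), thr, tolerance = 1)
  }
})

make_lmm_records <- function(effect = 0, seed = 1, n_per_group = 6,
                             n_mu = 5) {
  set.seed(seed)
  levels <- c(15, 35, 55, 70)
  rows <- list()
  for (g in c("A", "B")) for (p in seq_len(n_per_group)) {
    pid <- paste0(g, p)
    p_int <- rnorm(1, 0, 1)
    for (lv in levels) for (m in c("APB", "FDS")) for (u in seq_len(n_mu)) {
      thr <- runif(1, 0, 0.8 * lv)
      rate <- 10 + 0.15 * lv - 0.05 * thr + p_int + rnorm(1, 0, 2) +
        ifelse(g == "B" & lv == 35 & m == "APB", effect, 0)
      rows[[length(rows) + 1]] <- data.frame(
        rate = rate, group = g, level = lv, muscle = m,
        participant = pid, threshold = thr)
    }
  }
  do.call(rbind, rows)
}

test_that("mixed model: conditional R2 >= marginal R2 and null effects give
           CIs covering zero", {
  res <- fit_firing_lmm(make_lmm_records(effect = 0, seed = 2))
  expect_true(res$r2_marginal <= res$r2_conditional)
  expect_true(res$r2_conditional <= 1)
  cell <- res$contrasts[res$contrasts$level == "35" &
                          res$contrasts$muscle == "APB", ]
  expect_true(cell$lower.CL <= 0 && 0 <= cell$upper.CL)
  expect_error(fit_firing_lmm(make_lmm_records()[, 1:3]), "columns")
})

test_that("mixed model recovers a programmed group effect in the right
           cell", {
  res <- fit_firing_lmm(make_lmm_records(effect = 3, seed = 3))
  cell <- res$contrasts[res$contrasts$level == "35" &
                          res$contrasts$muscle == "APB", ]
  # contrast is A - B, so the programmed +3 Hz for B appears as -3
  expect_true(cell$lower.CL <= -3 && -3 <= cell$upper.CL)
  other <- res$contrasts[res$contrasts$level == "55" &
                           res$contrasts$muscle == "FDS", ]
  expect_true(other$lower.CL <= 0 && 0 <= other$upper.CL)
})

test_that("small cells are flagged for cautious interpretation", {
  recs <- make_lmm_records(seed = 4)
  drop <- recs$level == 15 & recs$muscle == "FDS" &
    !(recs$participant %in% c("A1", "B1"))
  recs <- recs[!drop | recs$level != 15 | recs$muscle != "FDS", ]
  keep <- !(recs$level == 15 & recs$muscle == "FDS") |
    recs$participant %in% c("A1", "B1")
  res <- fit_firing_lmm(recs[keep, ], min_cell_n = 10)
  cell <- res$contrasts[res$contrasts$level == "15" &
                          res$contrasts$muscle == "FDS", ]
  expect_true(cell$small_cell)
})
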