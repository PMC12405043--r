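# Synthetic motor-neuron-pool cohort generator.

test_that("pool thresholds follow the exponential spacing formula and twitch
           sizes grow with threshold", {
  pool <- generate_pool(30, seed = 51)
  # independently coded spacing oracle
  i <- 1:30; rr <- 30; tmax <- 0.65
  oracle <- tmax * (exp(log(rr) * (i - 1) / 29) - 1) / (rr - 1)
  expect_equal(pool$threshold, oracle, tolerance = 1e-12)
  expect_true(all(diff(pool$threshold) > 0))
  expect_true(all(diff(pool$twitch_amp) > 0))
  expect_equal(min(pool$threshold), 0)
  expect_equal(max(pool$threshold), 0.65)
})

test_that("degenerate single-unit pool and pool determinism", {
  p1 <- generate_pool(1, seed = 52)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$threshold, 0)
  expect_true(p1$twitch_amp > 0 && p1$twitch_ct > 0)
  pa <- generate_pool(12, seed = 53)
  pb <- generate_pool(12, seed = 53)
  expect_identical(pa, pb)
  expect_false(identical(pa$muap_amp, generate_pool(12, seed = 54)$muap_amp))
  expect_error(generate_pool(0), ">= 1")
})

test_that("a jitter-free unit under constant hold drive fires perfectly
           periodically at its programmed rate", {
  pool <- generate_pool(1, mvc_scale = 50, seed = 55, isi_cv = 0,
                        hysteresis = 0)
  quiet <- common_drive_spec(strength = 0, noise_sd = 0, slow_sd = 0)
  pr <- protocol_spec(force_levels = 0.1)
  tr <- simulate_trial(list(APB = pool, FDS = pool), quiet, pr, 0.1,
                       seed = 1)
  st <- tr$spikes$APB[[1]]
  hold <- st$times[st$times > 3 & st$times < 12]
  ipis <- diff(hold)
  expect_lt(sd(ipis) / mean(ipis), 1e-6)
  programmed <- min(30, 12 + 100 * 0.1)   # min_rate + gain * excess drive
  expect_equal(1 / mean(ipis), programmed, tolerance = 1e-3)
})

test_that("trials are reproducible from their seed and reject bad levels", {
  pools <- list(APB = generate_pool(8, 48, seed = 1),
                FDS = generate_pool(8, 72, seed = 2))
  dr <- common_drive_spec(strength = 0.3)
  pr <- protocol_spec()
  t1 <- simulate_trial(pools, dr, pr, 0.35, seed = 7)
  t2 <- simulate_trial(pools, dr, pr, 0.35, seed = 7)
  expect_identical(t1$force$samples, t2$force$samples)
  expect_identical(t1$emg$FDS, t2$emg$FDS)
  expect_identical(lapply(t1$spikes$APB, `[[`, "times"),
                   lapply(t2$spikes$APB, `[[`, "times"))
  t3 <- simulate_trial(pools, dr, pr, 0.35, seed = 8)
  expect_false(identical(t1$force$samples, t3$force$samples))
  expect_error(simulate_trial(pools, dr, pr, 1.2, seed = 1), "fraction")
})

test_that("series are time-aligned and spikes lie within the trial", {
  pools <- list(APB = generate_pool(10, 48, seed = 3),
                FDS = generate_pool(10, 72, seed = 4))
  pr <- protocol_spec()
  tr <- simulate_trial(pools, common_drive_spec(), pr, 0.55, seed = 9)
  dur <- trial_duration(pr)
  expect_equal(length(tr$force$samples) / tr$force$fs, dur, tolerance = 1e-3)
  expect_equal(nrow(tr$emg$APB) / tr$emg_fs, dur, tolerance = 1e-3)
  all_spikes <- unlist(lapply(unlist(tr$spikes, recursive = FALSE),
                              `[[`, "times"))
  expect_true(all(all_spikes >= 0 & all_spikes <= dur))
})

test_that("units are recruited in threshold order on the ramp", {
  pools <- list(APB = generate_pool(20, 48, seed = 5),
                FDS = generate_pool(20, 72, seed = 6))
  pr <- protocol_spec()
  tr <- simulate_trial(pools, common_drive_spec(strength = 0.3), pr, 0.70,
                       seed = 10)
  for (m in c("APB", "FDS")) {
    first <- vapply(tr$spikes[[m]], function(s) s$times[1], numeric(1))
    thr <- vapply(tr$spikes[[m]], `[[`, numeric(1), "true_threshold")
    expect_true(all(diff(first[order(thr)]) >= 0))
  }
})

test_that("mean hold force increases with target level for a fixed pool and
           seed", {
  pools <- list(APB = generate_pool(20, 48, seed = 11),
                FDS = generate_pool(20, 72, seed = 12))
  pr <- protocol_spec()
  hold_mean <- vapply(pr$force_levels, function(lv) {
    tr <- simulate_trial(pools, common_drive_spec(strength = 0.3), pr, lv,
                         seed = 13)
    i <- round((pr$pre_s + pr$ramp_s) * pr$force_fs):
      round((pr$pre_s + pr$ramp_s + pr$hold_s) * pr$force_fs)
    mean(tr$force$samples[i])
  }, numeric(1))
  expect_true(all(diff(hold_mean) > 0))
  # hold force tracks the target within a few percent of MVC
  targets <- pr$force_levels * (48 + 72)
  expect_true(all(abs(hold_mean - targets) / 120 < 0.05))
})

test_that("a cohort writes twelve bundles per participant with a
           deterministic manifest", {
  pr <- protocol_spec()   # 4 levels x 3 repeats
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gs <- default_group_specs()
  gs$dexterity$n_units <- 6; gs$strength$n_units <- 6
  m1 <- generate_cohort(gs, pr, n_per_group = 1, seed = 21, dir = d1)
  expect_equal(nrow(m1), 2 * 12)   # two groups, one participant each
  expect_equal(sum(m1$participant == "P01"), 12)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(all(file.exists(m1$force_file)))

  m2 <- generate_cohort(gs, pr, n_per_group = 1, seed = 21, dir = d2)
  same_cols <- setdiff(names(m1), c("force_file", "emg_file", "spikes_file"))
  expect_identical(m1[, same_cols], m2[, same_cols])
  expect_identical(unname(tools::md5sum(m1$force_file)),
                   unname(tools::md5sum(m2$force_file)))
  expect_identical(unname(tools::md5sum(m1$spikes_file)),
                   unname(tools::md5sum(m2$spikes_file)))
  expect_error(generate_cohort(gs, pr, n_per_group = 0), ">= 1")
})
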