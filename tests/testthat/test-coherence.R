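# Intermuscular coherence chain.

test_that("confidence limit follows 1 - 0.05^(1/(L-1)) and decreases in L", {
  expect_equal(confidence_limit(2), 0.95)
  expect_equal(confidence_limit(96), 1 - 0.05^(1 / 95))
  Ls <- c(2, 4, 8, 16, 96, 960)
  expect_true(all(diff(confidence_limit(Ls)) < 0))
  expect_error(confidence_limit(1), ">= 2")
})

test_that("segmentation arithmetic: a 4 s window in 460 ms segments gives
           L = 8 and a 2.17 Hz grid at 2222 Hz", {
  fs <- 2222
  n <- round(4 * fs)
  set.seed(1)
  sp <- estimate_spectra(rnorm(n), rnorm(n), fs = fs)
  expect_identical(sp$L, 8L)
  expect_equal(diff(sp$freqs[1:2]), 2.17, tolerance = 0.005)
  expect_identical(sp$segment_samples, 1022L)
  expect_error(estimate_spectra(rnorm(100), rnorm(100), fs = 2222),
               "fewer than one")
  expect_error(estimate_spectra(rnorm(n), rnorm(n - 1), fs = fs), "differ")
})

test_that("identical inputs give f_xy = f_xx and coherence exactly 1", {
  set.seed(2)
  x <- rnorm(2000)
  sp <- estimate_spectra(x, x, fs = 500)
  expect_equal(Re(sp$f_xy), sp$f_xx, tolerance = 1e-12)
  expect_equal(max(abs(Im(sp$f_xy))), 0, tolerance = 1e-12)
  co <- coherence(sp)
  expect_true(all(abs(co$R2[sp$f_xx > 0] - 1) < 1e-9))
})

test_that("coherence is bounded in [0, 1] for arbitrary inputs", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(1500); y <- 0.3 * x + rnorm(1500)
    co <- coherence(estimate_spectra(x, y, fs = 300))
    expect_true(all(co$R2 >= 0 & co$R2 <= 1))
  }
  sp <- estimate_spectra(rnorm(1022), rnorm(1022), fs = 2222)
  expect_identical(sp$L, 1L)
  expect_error(coherence(sp), "at least 2")
})

test_that("null exceedance rate of the confidence limit is ~5% for L = 8", {
  set.seed(99)
  n_rep <- 120
  exceed <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    co <- coherence(estimate_spectra(rnorm(8 * 1022), rnorm(8 * 1022),
                                     fs = 2222))
    exceed[i] <- mean(co$R2[-1] > co$CL)   # skip the demeaned DC bin
  }
  expect_gt(mean(exceed), 0.03)
  expect_lt(mean(exceed), 0.07)
})

test_that("envelope preprocessing: stop-band tones vanish, pass-band tones
           give the analytic constant envelope", {
  fs <- 1000
  tt <- seq(0, 6 - 1 / fs, by = 1 / fs)
  win <- window_at(1, 4)
  x50 <- sqrt(2) * sin(2 * pi * 50 * tt)   # unit variance
  env <- preprocess_envelope(x50, win, fs)
  expect_equal(length(env$samples), 4000)
  # envelope of a unit-variance tone is the constant sqrt(2)
  core <- env$samples[200:3800]            # away from filter edges
  expect_equal(mean(core), sqrt(2), tolerance = 0.01)
  expect_lt(sd(core), 0.02)

  # a 10 Hz tone is removed by the 20 Hz high-pass: tiny envelope relative
  # to a pass-band tone, but unit variance is re-imposed after filtering,
  # so compare the filtered signal amplitudes directly
  hp <- signal::butter(4, 20 / (fs / 2), "high")
  x10 <- signal::filtfilt(hp, sin(2 * pi * 10 * tt))
  expect_lt(sd(x10), 0.05)

  expect_error(preprocess_envelope(rep(1, 6000), win, fs), "zero-variance")
  expect_error(preprocess_envelope(x50, window_at(4, 4), fs), "outside")
})

test_that("pooling k copies of one record reproduces it and is
           order-invariant", {
  set.seed(3)
  x <- rnorm(4000); y <- rnorm(4000)
  sp <- estimate_spectra(x, y, fs = 1000)
  co <- coherence(sp)
  pooled <- pool_coherence(list(sp, sp, sp))
  expect_equal(pooled$R2, co$R2, tolerance = 1e-12)
  expect_identical(pooled$L, 3L * sp$L)

  sp2 <- estimate_spectra(rnorm(4000), rnorm(4000), fs = 1000)
  p12 <- pool_coherence(list(sp, sp2))
  p21 <- pool_coherence(list(sp2, sp))
  expect_equal(p12$R2, p21$R2, tolerance = 1e-12)

  bad <- estimate_spectra(rnorm(2000), rnorm(2000), fs = 500)
  expect_error(pool_coherence(list(sp, bad)), "mismatched")
})

test_that("pooled null exceedance stays near 5%", {
  set.seed(4)
  rates <- replicate(40, {
    specs <- lapply(1:6, function(i) {
      estimate_spectra(rnorm(8 * 1022), rnorm(8 * 1022), fs = 2222)
    })
    pc <- pool_coherence(specs)
    mean(pc$R2[-1] > pc$CL)
  })
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})

test_that("within-group heterogeneity is zero for identical records, flags
           a deviant record, and ignores record order", {
  set.seed(5)
  sp <- estimate_spectra(rnorm(4000), rnorm(4000), fs = 1000)
  het <- within_group_heterogeneity(list(sp, sp, sp))
  expect_true(all(abs(het$chi2) < 1e-12))
  expect_true(all(!het$flag))

  # one record with genuine common signal among nulls
  fs <- 1000
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 20 * tt)
  mk_null <- function() estimate_spectra(rnorm(4000), rnorm(4000), fs = fs)
  mk_coh <- function() {
    estimate_spectra(tone + 0.5 * rnorm(4000), tone + 0.5 * rnorm(4000),
                     fs = fs)
  }
  flags20 <- replicate(20, {
    specs <- c(replicate(4, mk_null(), simplify = FALSE), list(mk_coh()))
    het <- within_group_heterogeneity(specs)
    bin20 <- which.min(abs(het$freq - 20))
    het$flag[bin20]
  })
  expect_gt(mean(flags20), 0.8)

  specs <- c(replicate(2, mk_null(), simplify = FALSE), list(mk_coh()))
  h1 <- within_group_heterogeneity(specs)
  h2 <- within_group_heterogeneity(rev(specs))
  expect_equal(h1$chi2, h2$chi2, tolerance = 1e-12)
  expect_error(within_group_heterogeneity(specs[1]), "at least 2")
})

test_that("between-group difference is zero for identical groups and
           antisymmetric under swapping", {
  set.seed(6)
  mk <- function() {
    pool_coherence(lapply(1:3, function(i) {
      estimate_spectra(rnorm(4000), rnorm(4000), fs = 1000)
    }))
  }
  a <- mk(); b <- mk()
  same <- between_group_difference(a, a)
  expect_true(all(same$statistic == 0))
  expect_true(all(same$direction == "ns"))

  ab <- between_group_difference(a, b)
  ba <- between_group_difference(b, a)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_equal(sum(ab$direction == "a>b"), sum(ba$direction == "b>a"))
})

test_that("percent-significant-trials is a per-bin exceedance percentage", {
  set.seed(7)
  cohs <- lapply(1:10, function(i) {
    coherence(estimate_spectra(rnorm(8 * 1022), rnorm(8 * 1022), fs = 2222))
  })
  pct <- percent_significant_trials(cohs)
  expect_true(all(pct$pct_significant >= 0 & pct$pct_significant <= 100))
  # all-null trials: around 5% on average across bins
  expect_lt(mean(pct$pct_significant[-1]), 10)
  # identical significant trials at one bin give 100% there
  hand <- 100 * rowMeans(vapply(cohs, function(co) co$R2 > co$CL,
                                logical(length(cohs[[1]]$freqs))))
  expect_equal(pct$pct_significant, hand)
})

test_that("band averages partition the grid and match hand-computed means", {
  freqs <- seq(0, 100, by = 2.174)
  co <- structure(list(freqs = freqs, R2 = rep(0.2, length(freqs)),
                       L = 96, CL = confidence_limit(96)),
                  class = "coherence_spectrum")
  ba <- band_average(co)
  expect_equal(ba$mean_coherence, rep(0.2, 3))

  co$R2[which.min(abs(freqs - 20))] <- 0.9
  ba <- band_average(co)
  expect_gt(ba$mean_coherence[ba$band == "beta"], 0.2)
  expect_equal(ba$mean_coherence[ba$band == "alpha"], 0.2)
  expect_equal(ba$mean_coherence[ba$band == "gamma"], 0.2)
  # hand-computed beta mean
  sel <- freqs >= 16 & freqs < 30
  expect_equal(ba$mean_coherence[ba$band == "beta"], mean(co$R2[sel]))

  short <- structure(list(freqs = seq(0, 35, by = 2.174),
                          R2 = rep(0.1, 17), L = 8, CL = 0.3),
                     class = "coherence_spectrum")
  expect_warning(ba2 <- band_average(short), "gamma")
  expect_false("gamma" %in% ba2$band)
})

test_that("crosstalk flag requires high coherence in every band at once", {
  freqs <- seq(0, 100, by = 2.174)
  mk <- function(R2) structure(list(freqs = freqs, R2 = R2, L = 96,
                                    CL = 0.03), class = "coherence_spectrum")
  expect_true(crosstalk_qc(mk(rep(0.9, length(freqs)))))
  expect_false(crosstalk_qc(mk(rep(0.1, length(freqs)))))
  beta_only <- rep(0.1, length(freqs))
  beta_only[freqs >= 16 & freqs < 30] <- 0.9
  expect_false(crosstalk_qc(mk(beta_only)))
})

test_that("the envelope pipeline is deterministic", {
  set.seed(8)
  x <- rnorm(12000)
  win <- window_at(0.5, 4)
  e1 <- preprocess_envelope(x, win, 2222)
  e2 <- preprocess_envelope(x, win, 2222)
  expect_identical(e1$samples, e2$samples)
  s1 <- estimate_spectra(e1, e1)
  s2 <- estimate_spectra(e2, e2)
  expect_identical(s1$f_xx, s2$f_xx)
})
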