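fs <- 1024

test_that("band-pass keeps mid-band tones and removes DC and slow drift", {
  t <- (0:(60 * fs - 1)) / fs
  tone <- sin(2 * pi * 8 * t)
  out <- bandpass_filter(tone, fs)
  interior <- (fs / 2):(length(t) - fs / 2)   # away from boundary ringing
  expect_lt(max(abs(out - tone)[interior]), 0.02)   # amplitude within 2%

  dc <- bandpass_filter(rep(5, 60 * fs), fs)
  expect_lt(max(abs(dc)), 0.05)                     # < 1% of the DC level

  drift <- sin(2 * pi * 0.1 * t)
  mix <- drift + tone
  out <- bandpass_filter(mix, fs)
  resid_drift <- out - tone
  expect_lt(mean(resid_drift^2) / mean(drift^2), 0.01)   # >= 20 dB down
  # the tone itself survives within 2% rms
  expect_lt(sqrt(mean((out - tone)^2) / mean(tone^2)), 0.15)
  expect_error(bandpass_filter(tone, fs = 150), "sampling rate")
})

test_that("band-pass handles awkward lengths without edge artefacts", {
  n <- 47123   # not FFT-friendly: exercises the reflect-extend path
  dc <- bandpass_filter(rep(2, n), fs)
  expect_lt(max(abs(dc)), 0.02)
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 8 * t)
  out <- bandpass_filter(tone, fs)
  expect_lt(max(abs(out - tone)[500:(n - 500)]), 0.02)
})

test_that("epoching yields floor(duration / epoch_len) non-overlapping epochs", {
  cases <- list(c(60, 30), c(7.3, 3), c(2.0, 1))
  for (cs in cases) {
    rec <- tone_recording(8, duration = cs[1])
    es <- epoch_signal(rec)
    expect_identical(dim(es$epochs)[2], as.integer(cs[2]))
    expect_identical(dim(es$epochs)[1], 2048L)
  }
  expect_error(epoch_signal(tone_recording(8, duration = 1.5)),
               "shorter than one epoch")
})

test_that("amplitude artifact rule drops exactly the contaminated epoch", {
  set.seed(4)
  rec <- simulate_trial_eeg(quick_cfg(), "CTR", 1, condition = "calib",
                            duration = 30, seed = 4)
  es <- reject_artifacts(epoch_signal(rec))
  expect_true(all(es$keep))                  # clean record: no rejections
  expect_identical(nrow(es$rejection), 0L)

  spiky <- rec
  spike_at <- 5 * 2048 + 1000                # inside epoch 6
  spiky$samples[spike_at, 3] <- 50 * max(abs(rec$samples[, 3]))
  es2 <- reject_artifacts(epoch_signal(spiky))
  expect_identical(which(!es2$keep), 6L)
  expect_match(es2$rejection$reason[1], "peak amplitude")

  es3 <- reject_artifacts(epoch_signal(spiky), z_threshold = Inf)
  expect_true(all(es3$keep))                 # infinite threshold: identity

  allbad <- rec
  allbad$samples[seq(1, nrow(allbad$samples), by = 2048), 1] <- 1e6
  expect_error(reject_artifacts(epoch_signal(allbad)), "all .* epochs rejected")
})

test_that("absolute power concentrates an on-grid tone in its single bin", {
  rec <- tone_recording(8, duration = 10)
  ps <- absolute_power(epoch_signal(rec))
  i8 <- which(theta_grid() == 8)
  expect_gt(ps$ap[i8, 1] / sum(ps$ap[, 1]), 0.99)
  expect_equal(unname(ps$ap[i8, 1]), 0.5, tolerance = 1e-9)  # mean square of unit sine
})

test_that("equal-power tones at 6 and 9 Hz give equal bins", {
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 6 * t) + sin(2 * pi * 9 * t)
  rec <- multisite_recording(cbind(x, x, x, x), fs,
                             meta = list(condition = "test"))
  ps <- absolute_power(epoch_signal(rec))
  expect_equal(ps$ap[which(theta_grid() == 6), 1],
               ps$ap[which(theta_grid() == 9), 1], tolerance = 1e-9)
})

test_that("white-noise spectrum is flat over the grid", {
  set.seed(11)
  m <- matrix(rnorm(2048 * 1000 * 4), ncol = 4)
  rec <- multisite_recording(m, fs, meta = list(condition = "calib"))
  ps <- absolute_power(epoch_signal(rec))
  expect_lt(max(ps$ap[, 1]) / min(ps$ap[, 1]), 1.3)
})

test_that("absolute power matches a directly coded DFT oracle", {
  set.seed(21)
  m <- matrix(rnorm(3 * 2048 * 4), ncol = 4)
  rec <- multisite_recording(m, fs, meta = list(condition = "calib"))
  es <- epoch_signal(rec)
  ps <- absolute_power(es)
  for (ch in 1:4) {
    oracle <- brute_force_ap(es$epochs[, , ch], fs)
    expect_equal(ps$ap[, ch], unname(oracle), tolerance = 1e-9)
  }
})

test_that("relative power sums to 100 and follows the arithmetic", {
  rec <- tone_recording(8, duration = 10)
  rp <- relative_power(absolute_power(epoch_signal(rec)))
  expect_equal(unname(colSums(rp$rp)), rep(100, 4), tolerance = 1e-9)
  i8 <- which(theta_grid() == 8)
  expect_gt(rp$rp[i8, 1], 99)
  # uniform spectrum: every bin 100/17
  ps <- absolute_power(epoch_signal(rec))
  ps$ap[] <- 3.7
  expect_equal(unname(relative_power(ps)$rp[, 1]), rep(100 / 17, 17),
               tolerance = 1e-9)
  # toy ratio 1:3 across two bins
  ps$ap[] <- 0
  ps$ap[c(2, 5), ] <- c(1, 3)
  expect_equal(unname(relative_power(ps)$rp[c(2, 5), 1]), c(25, 75),
               tolerance = 1e-9)
  ps$ap[] <- 0
  expect_error(relative_power(ps), "zero total .* power in channel SUM")
})

test_that("relative power and peak frequency are exactly scale invariant", {
  rec <- simulate_trial_eeg(quick_cfg(), "CTR", 2, condition = "calib",
                            duration = 12, seed = 9)
  scaled <- rec
  scaled$samples <- rec$samples * 17.3
  rp1 <- relative_power(absolute_power(epoch_signal(rec)))
  rp2 <- relative_power(absolute_power(epoch_signal(scaled)))
  expect_equal(rp1$rp, rp2$rp, tolerance = 1e-12)
  expect_identical(peak_frequency(rp1)$peak_freq, peak_frequency(rp2)$peak_freq)
})

test_that("natural-log power maps known values and flags zeros", {
  rec <- tone_recording(8, duration = 10)
  ps <- absolute_power(epoch_signal(rec))
  ps$ap[] <- exp(1)
  expect_equal(unname(log_absolute_power(ps)[1, 1]), 1)
  ps$ap[] <- 1
  expect_equal(unname(log_absolute_power(ps)[5, 2]), 0)
  ps$ap[3, 1] <- 0
  out <- log_absolute_power(ps)
  expect_true(is.na(out[3, 1]))
  expect_true(attr(out, "excluded")[3, 1])
})

test_that("peak frequency uses the band and the lowest-frequency tie rule", {
  rec <- tone_recording(8, duration = 10)
  rp <- relative_power(absolute_power(epoch_signal(rec)))
  expect_equal(peak_frequency(rp)$peak_freq, rep(8, 4))
  # uniform relative power: tie resolves to the band's lower edge
  ps <- absolute_power(epoch_signal(rec))
  ps$ap[] <- 1
  expect_equal(peak_frequency(relative_power(ps))$peak_freq, rep(5, 4))
  expect_error(peak_frequency(rp, band = c(3, 10)), "within the 4-12")
})

test_that("an off-grid tone quantises to a neighbouring bin", {
  rec <- tone_recording(7.25, duration = 10)
  pk <- peak_frequency(relative_power(absolute_power(epoch_signal(rec))))
  expect_true(all(pk$peak_freq %in% c(7.0, 7.5)))
})

test_that("the theta oscillator honours its contract", {
  expect_error(make_theta_oscillator(0, 1, 10, fs), "invalid parameter")
  expect_error(make_theta_oscillator(600, 1, 10, fs), "invalid parameter")
  x <- make_theta_oscillator(7.5, 0.5, 60, fs, variance = 2.5, seed = 1)
  expect_equal(mean(x^2), 2.5, tolerance = 0.05 * 2.5)
  expect_equal(mean(x), 0, tolerance = 1e-9)

  # pure-tone limit: the pipeline recovers the frequency exactly
  y <- make_theta_oscillator(8, 0, 60, fs, seed = 2)
  rec <- multisite_recording(cbind(y, y, y, y), fs,
                             meta = list(condition = "calib"))
  pk <- peak_frequency(relative_power(absolute_power(epoch_signal(rec))))
  expect_equal(pk$peak_freq, rep(8, 4))
})

test_that("a 0.5 Hz-wide oscillator peaks within 0.25 Hz of f0", {
  x <- make_theta_oscillator(8, 0.5, 120, fs, seed = 1)
  # oracle: long-window periodogram of the raw signal at fine resolution
  per <- abs(fft(x))^2
  f <- (seq_along(per) - 1) * fs / length(per)
  sel <- f >= 4 & f <= 12
  f_peak <- f[sel][which.max(per[sel])]
  expect_lt(abs(f_peak - 8), 0.25)
  # and through the pipeline's own 2-s-epoch spectrum
  rec <- multisite_recording(cbind(x, x, x, x), fs,
                             meta = list(condition = "calib"))
  pk <- peak_frequency(relative_power(absolute_power(epoch_signal(rec))))
  expect_lt(abs(pk$peak_freq[1] - 8), 0.25 + 1e-12)
})
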