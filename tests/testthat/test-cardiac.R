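test_that("ECG filter removes DC and mains while preserving the passband", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  # constant offset: high-pass drives the mean to zero
  const <- waveform_channel(rep(2.5, length(t)), fs, role = "ecg")
  expect_lt(abs(mean(filter_ecg(const)$values)), 1e-3)
  # 50 Hz tone attenuated by >= 20 dB
  tone <- waveform_channel(sin(2 * pi * 50 * t), fs, role = "ecg")
  out <- filter_ecg(tone)
  expect_gt(20 * log10(oracle_tone_amplitude(tone$values, fs, 50) /
                         oracle_tone_amplitude(out$values, fs, 50)), 20)
  # 1.5 Hz passband tone preserved within 5%
  pass <- waveform_channel(sin(2 * pi * 1.5 * t), fs, role = "ecg")
  kept <- oracle_tone_amplitude(filter_ecg(pass)$values, fs, 1.5)
  expect_lt(abs(kept - 1), 0.05)
  # sampling rate too low for the notch is rejected
  slow <- waveform_channel(sin(2 * pi * 2 * seq(0, 30, by = 1 / 100)), 100,
                           role = "ecg")
  expect_error(filter_ecg(slow), "notch")
})

test_that("R peaks are recovered exactly on clean synthetic ECG of any polarity", {
  p <- fix_profile(mean_rr = 800, lf_depth = 30, hf_depth = 20,
                   rr_noise_sd = 15)
  truth <- generate_rr_series(p, 300, seed = 21)$times
  for (pol in c(1, -1)) {
    ecg <- synthesize_ecg(truth, fs = 250, duration = 300, polarity = pol)
    pk <- detect_r_peaks(filter_ecg(ecg))
    expect_equal(length(pk$times), length(truth))
    expect_lt(max(abs(pk$times - truth)) * 250, 1 + 1e-6)
  }
})

test_that("flat signal yields an explicit empty peak result", {
  flat <- waveform_channel(rep(0, 250 * 30), 250, role = "ecg")
  pk <- detect_r_peaks(flat)
  expect_s3_class(pk, "event_series")
  expect_length(pk$times, 0)
})

test_that("RR correction flags ectopic-scale outliers and preserves clean series", {
  clean <- rr_series(cumsum(c(0, rep(0.8, 50))))
  out <- correct_rr_intervals(clean)
  expect_equal(sum(out$flags), 0)
  expect_true(attr(out, "usable"))
  expect_equal(out$intervals, clean$intervals)

  # one 3000 ms interval amid ~800 ms neighbours: flagged, replaced locally
  iv <- rep(800, 40)
  iv[20] <- 3000
  rr <- rr_series(cumsum(c(0, iv)) / 1000)
  fixed <- correct_rr_intervals(rr)
  expect_true(attr(fixed, "usable"))
  expect_gt(attr(fixed, "n_corrected"), 0)
  # a 3000ms interval among 800s is a run of missed beats: split into
  # plausible sub-intervals close to the local median
  expect_true(all(abs(fixed$intervals[fixed$flags] - 800) < 100))
  # total time preserved by the split rule
  expect_equal(sum(fixed$intervals), sum(iv), tolerance = 1e-9)

  # missed beat: one interval the sum of two neighbours, split in two
  iv2 <- rep(820, 30)
  iv2[15] <- 1640
  rr2 <- rr_series(cumsum(c(0, iv2)) / 1000)
  fixed2 <- correct_rr_intervals(rr2)
  expect_equal(length(fixed2$intervals), 31)
  expect_true(all(abs(fixed2$intervals[fixed2$flags] - 820) < 100))
})

test_that("recordings with excessive artifact load are marked unusable", {
  set.seed(8)
  iv <- rep(800, 40)
  iv[seq(1, 40, by = 3)] <- 2200  # > 20% aberrant
  rr <- rr_series(cumsum(c(0, iv)) / 1000)
  out <- correct_rr_intervals(rr)
  expect_false(attr(out, "usable"))
  expect_gt(attr(out, "frac_flagged"), 0.2)
})

test_that("segment selection windows beats and rejects short recordings", {
  rr <- rr_series(seq(0, 720, by = 0.9))
  seg <- select_segment(rr, length_s = 660, start_s = 60)
  expect_lte(rr_span(seg), 660)
  expect_gte(rr_span(seg), 660 - 2 * 0.9)
  expect_equal(seg$times[1], 0, tolerance = 0.9)

  exact <- rr_series(seq(0, 660, by = 1))
  seg2 <- select_segment(exact, length_s = 660)
  expect_equal(seg2$intervals, exact$intervals)

  short <- rr_series(seq(0, 300, by = 1))
  expect_error(select_segment(short, length_s = 660), "available")
})

test_that("time-domain metrics match closed forms on constructed series", {
  td <- hrv_time_domain(rep(1000, 60))
  expect_equal(td$heart_rate, 60)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)

  alt <- rep(c(800, 860), 25)
  td2 <- hrv_time_domain(alt)
  expect_equal(td2$rmssd, 60)
  expect_equal(td2$pnn50, 100)
})

test_that("time-domain metrics and ApEn equal brute-force oracles on random series", {
  withr::with_seed(42, {
    for (i in 1:100) {
      x <- stats::rnorm(50, 900, 60)
      td <- hrv_time_domain(x)
      expect_equal(td$rr_mean, oracle_mean(x), tolerance = 1e-9)
      expect_equal(td$sdnn, oracle_sd(x), tolerance = 1e-9)
      expect_equal(td$rmssd, oracle_rmssd(x), tolerance = 1e-9)
      expect_equal(td$pnn50, oracle_pnn50(x), tolerance = 1e-9)
      expect_equal(td$heart_rate, oracle_heart_rate(x), tolerance = 1e-9)
    }
    for (i in 1:5) {
      x <- stats::rnorm(100, 900, 50)
      expect_equal(approximate_entropy(x), oracle_apen(x), tolerance = 1e-9)
    }
  })
})

test_that("ApEn behaves as a regularity statistic", {
  expect_equal(approximate_entropy(rep(900, 80), r = 1), 0)
  withr::with_seed(31, {
    t <- seq(0, 120, by = 0.8)
    sine <- 900 + 50 * sin(2 * pi * 0.1 * t)
    shuffled <- sample(sine)
    expect_gt(approximate_entropy(shuffled), approximate_entropy(sine))
  })
  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "m \\+ 2")
})

test_that("Welch band powers separate LF from HF modulations", {
  p_hf <- fix_profile(mean_rr = 1000, hf_depth = 40, hf_freq = 0.25)
  fd_hf <- hrv_frequency_domain(
    rr_series(generate_rr_series(p_hf, 660, seed = 1)$times)
  )
  expect_gt(fd_hf$hf / (fd_hf$lf + fd_hf$hf), 0.95)

  p_lf <- fix_profile(mean_rr = 1000, lf_depth = 40, lf_freq = 0.10)
  fd_lf <- hrv_frequency_domain(
    rr_series(generate_rr_series(p_lf, 660, seed = 1)$times)
  )
  expect_gt(fd_lf$lf / (fd_lf$lf + fd_lf$hf), 0.95)

  for (fd in list(fd_hf, fd_lf)) {
    expect_gte(fd$lfn, 0); expect_lte(fd$lfn, 1)
    expect_gte(fd$hfn, 0); expect_lte(fd$hfn, 1)
    expect_lte(fd$lf + fd$hf, fd$total_power * (1 + 1e-9))
    expect_equal(fd$ln_hf, log(fd$hf))
  }
})

test_that("zero HF power is reported as missing, never infinite", {
  rr <- rr_series(cumsum(c(0, rep(1, 200))))
  fd <- hrv_frequency_domain(rr)
  expect_true(is.na(fd$ln_hf))
  expect_true(is.na(fd$lf_hf_ratio))
})

test_that("spectral metrics are stable across window start offsets", {
  p <- fix_profile(lf_depth = 40, hf_depth = 25, rr_noise_sd = 10)
  rr <- rr_series(generate_rr_series(p, 900, seed = 12)$times)
  f0 <- hrv_frequency_domain(select_segment(rr, 660, 0))
  f1 <- hrv_frequency_domain(select_segment(rr, 660, 120))
  expect_lt(abs(f0$hfn - f1$hfn), 0.1)
  expect_lt(abs(log(f0$hf) - log(f1$hf)), 0.5)
})

test_that("mean-RR correction scales powers by the stated multiplier", {
  base <- list(lf = 0.01, hf = 0.004)
  out <- sacha_correction(base, mean_rr = 800)
  expect_equal(out$sacha_multiplier, 0.8)
  expect_equal(out$hf_c, 0.0032)
  expect_equal(out$lf_c, 0.008)
  expect_equal(out$ln_hf_c, log(0.0032))
  # multiplier of exactly 1 leaves powers untouched
  ident <- sacha_correction(base, mean_rr = 1000)
  expect_equal(ident$hf_c, base$hf)
  expect_equal(ident$lf_c, base$lf)
})

test_that("full cardiac path recovers the generator mean RR within 1 ms", {
  p <- fix_profile(mean_rr = 850, lf_depth = 35, hf_depth = 22,
                   rr_noise_sd = 15)
  truth <- generate_rr_series(p, 720, seed = 33)
  ecg <- synthesize_ecg(truth$times, fs = 250, duration = 720)
  res <- cardiac_features(ecg, analysis_config(), start_s = 30)
  expect_true(res$usable)
  keep <- truth$times >= 30 & truth$times <= 690
  expect_lt(abs(res$features[["rr_mean"]] -
                  mean(diff(truth$times[keep]) * 1000)), 1)
  expect_named(res$features, cardiac_feature_names())
})
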