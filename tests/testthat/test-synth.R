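test_that("degenerate profile yields a metronome tachogram", {
  p <- fix_profile(mean_rr = 1000)
  rr <- generate_rr_series(p, 300, seed = 3)
  expect_true(all(abs(rr$intervals - 1000) < 1e-9))
  expect_equal(stats::sd(rr$intervals), 0)
  expect_lte(max(rr$times), 300)
})

test_that("rr generation is deterministic and respects profile invariants", {
  p <- fix_profile(lf_depth = 30, hf_depth = 20, rr_noise_sd = 20)
  a <- generate_rr_series(p, 200, seed = 77)
  b <- generate_rr_series(p, 200, seed = 77)
  expect_identical(a$intervals, b$intervals)
  c <- generate_rr_series(p, 200, seed = 78)
  expect_false(identical(a$intervals, c$intervals))
  expect_true(abs(mean(a$intervals) - 900) < 30)
})

test_that("invalid profiles are rejected with a diagnostic", {
  expect_error(condition_profile("X", mean_rr = 250), "mean_rr")
  expect_error(condition_profile("X", mean_rr = 900, ie_ratio = 0),
               "ie_ratio")
  expect_error(condition_profile("X", mean_rr = 600, lf_depth = 200,
                                 hf_depth = 90, rr_noise_sd = 50),
               "mean_rr/2")
  expect_error(condition_profile("X", mean_rr = 900, hr_entropy_mix = 1.2),
               "hr_entropy_mix")
})

test_that("single-frequency HF modulation lands in the HF band downstream", {
  p <- fix_profile(mean_rr = 1000, hf_depth = 40, hf_freq = 0.25)
  rr <- rr_series(generate_rr_series(p, 660, seed = 11)$times)
  fd <- hrv_frequency_domain(rr)
  expect_gt(fd$hf / (fd$lf + fd$hf), 0.95)
  # band power of an A-sinusoid is A^2/2
  expect_lt(abs(fd$hf - 800) / 800, 0.15)
})

test_that("synthetic ECG places one QRS complex per beat, recoverable exactly", {
  r_times <- seq(0.5, 119.5, by = 1)
  ecg <- synthesize_ecg(r_times, fs = 250, duration = 120)
  pk <- detect_r_peaks(filter_ecg(ecg))
  expect_equal(length(pk$times), length(r_times))
  expect_lt(max(abs(pk$times - r_times)), 1 / 250 + 1e-9)
  # constructed 1 s spacing means 60 bpm downstream
  td <- hrv_time_domain(rr_series(pk$times))
  expect_equal(td$heart_rate, 60, tolerance = 1e-3)
})

test_that("powerline toggle adds a mains tone that the ECG filter removes", {
  r_times <- seq(0.5, 59.5, by = 0.9)
  dirty <- synthesize_ecg(r_times, fs = 250, duration = 60, powerline = TRUE)
  clean <- filter_ecg(dirty)
  amp_pre <- oracle_tone_amplitude(dirty$values, 250, 50)
  amp_post <- oracle_tone_amplitude(clean$values, 250, 50)
  expect_gt(amp_pre, 0.05)
  expect_gt(20 * log10(amp_pre / amp_post), 20)
})

test_that("respiration waveform carries exact phase asymmetry and amplitude", {
  p <- fix_profile(ie_ratio = 1.0, resp_amp = 200)
  sr <- synthesize_respiration(p, 300, seed = 5)
  pre <- preprocess_respiration(sr$wave)
  rf <- resp_features(correct_bb_intervals(detect_breaths(pre)), pre)
  expect_equal(rf$phase_ratio, 1.0, tolerance = 0.02)
  expect_equal(rf$resp_rate, 15, tolerance = 0.05)

  # amplitude linearity: doubling resp_amp doubles the measured excursion
  p2 <- fix_profile(ie_ratio = 1.0, resp_amp = 400)
  sr2 <- synthesize_respiration(p2, 300, seed = 5)
  pre2 <- preprocess_respiration(sr2$wave)
  rf2 <- resp_features(correct_bb_intervals(detect_breaths(pre2)), pre2)
  expect_equal(rf2$amplitude / rf$amplitude, 2, tolerance = 0.05)
})

test_that("injected breath jitter is recovered as SDBB at 11-minute duration", {
  p <- fix_profile(bb_jitter_sd = 200)
  sr <- synthesize_respiration(p, 660, seed = 9)
  pre <- preprocess_respiration(sr$wave)
  rf <- resp_features(correct_bb_intervals(detect_breaths(pre)), pre)
  expect_lt(abs(rf$sdbb - 200) / 200, 0.15)
})

test_that("cohort generation is deterministic with consistent ground truth", {
  a <- generate_cohort(n_subjects = 2, duration_s = 150, master_seed = 5)
  b <- generate_cohort(n_subjects = 2, duration_s = 150, master_seed = 5)
  expect_identical(a$recordings[[1]]$ecg$values, b$recordings[[1]]$ecg$values)
  expect_identical(a$recordings[[4]]$thoracic$values,
                   b$recordings[[4]]$thoracic$values)
  for (rec in a$recordings) {
    expect_true(all(diff(rec$truth_r_times) > 0))
    expect_lte(max(rec$truth_r_times), rec$duration_s)
    # truth intervals equal the generated series exactly
    expect_equal(diff(rec$truth_r_times) * 1000, rec$truth_rr_ms)
  }
  expect_equal(nrow(a$manifest), 6)
  ti <- a$manifest$trance_intensity
  expect_true(all(is.na(ti[a$manifest$condition != "SICT"])))
  expect_true(all(ti[a$manifest$condition == "SICT"] %in% 3:10))
})

test_that("empty cohorts are valid and duplicate subjects are rejected", {
  z <- generate_cohort(n_subjects = 0, duration_s = 150)
  expect_equal(length(z$recordings), 0)
  expect_equal(nrow(z$manifest), 0)
  expect_error(
    generate_cohort(n_subjects = 2, duration_s = 150,
                    subject_ids = c("S1", "S1")),
    "duplicate"
  )
})

test_that("each generator knob moves its paired downstream feature", {
  profs <- default_condition_profiles()
  lo <- profs$Rest
  hi <- profs$SICT
  cfg <- analysis_config(segment_s = 240, welch_seg_s = 60)
  feat <- function(p, seed) {
    rr <- rr_series(generate_rr_series(p, 250, seed = seed)$times)
    rr <- select_segment(rr, 240, 0)
    td <- hrv_time_domain(rr)
    fd <- hrv_frequency_domain(rr, welch_seg_s = 60)
    sr <- synthesize_respiration(p, 250, seed = seed + 1)
    pre <- preprocess_respiration(sr$wave)
    rf <- resp_features(correct_bb_intervals(detect_breaths(pre)), pre)
    c(hr = td$heart_rate, hfn = fd$hfn, amp = rf$amplitude,
      phase = rf$phase_ratio, sdbb = rf$sdbb)
  }
  f_lo <- rowMeans(sapply(1:4, function(s) feat(lo, 1000 + s)))
  f_hi <- rowMeans(sapply(1:4, function(s) feat(hi, 2000 + s)))
  expect_gt(f_hi[["hr"]], f_lo[["hr"]])        # shorter mean RR -> higher HR
  expect_lt(f_hi[["hfn"]], f_lo[["hfn"]])      # reduced HF depth
  expect_gt(f_hi[["amp"]], f_lo[["amp"]])      # larger belt excursion
  expect_gt(f_hi[["phase"]], f_lo[["phase"]])  # raised I/E ratio
  expect_gt(f_hi[["sdbb"]], f_lo[["sdbb"]])    # larger breath jitter
})
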