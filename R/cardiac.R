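#' Preprocess a raw ECG channel
#'
#' Applies a zero-phase (forward-backward) order-5 Butterworth high-pass at
#' 0.5 Hz to remove baseline drift, followed by a zero-phase Butterworth
#' band-stop notch around the mains frequency to remove powerline
#' interference. Output length equals input length.
#'
#' @param raw a `waveform_channel` (ECG), fs >= 100 Hz, duration >= 10 s.
#' @param highpass high-pass cut-off, Hz.
#' @param order Butterworth order of the high-pass.
#' @param mains_freq mains frequency, Hz (50 in Europe, 60 elsewhere).
#' @param notch_halfwidth half-width of the notch stop band, Hz.
#' @return filtered `waveform_channel`.
#' @export
filter_ecg <- function(raw, highpass = 0.5, order = 5, mains_freq = 50,
                       notch_halfwidth = 2) {
  stopifnot(inherits(raw, "waveform_channel"))
  if (raw$fs < 100) stop_trancehrv("ECG filtering requires fs >= 100 Hz")
  if (wf_duration(raw) < 10) stop_trancehrv("ECG filtering requires >= 10 s of signal")
  nyq <- raw$fs / 2
  if (mains_freq + notch_halfwidth >= nyq) {
    stop_trancehrv(
      "sampling rate %.0f Hz too low to notch %.0f Hz (needs fs > %.0f Hz)",
      raw$fs, mains_freq, 2 * (mains_freq + notch_halfwidth)
    )
  }
  hp <- signal::butter(order, highpass / nyq, type = "high")
  x <- signal::filtfilt(hp, raw$values - mean(raw$values))
  notch <- signal::butter(2, c(mains_freq - notch_halfwidth,
                               mains_freq + notch_halfwidth) / nyq,
                          type = "stop")
  x <- signal::filtfilt(notch, x)
  waveform_channel(x, raw$fs, role = raw$role)
}

#' Detect R peaks in a preprocessed ECG
#'
#' Derivative-square-integrate detector with adaptive thresholding: the
#' signal is band-passed to the QRS band (5-15 Hz), differentiated, squared
#' and smoothed with a 150 ms moving window; candidate peaks of the
#' integrated energy are accepted against a running signal/noise threshold
#' (Pan-Tompkins style) with a 200 ms refractory period. Accepted candidates
#' are then refined to the local extremum of the input ECG, with lead
#' polarity resolved globally, so clean peaks land on the true R sample.
#'
#' @param ecg a filtered `waveform_channel`.
#' @param refractory minimum inter-beat distance, s.
#' @return an `event_series` of R-peak times (possibly empty).
#' @export
detect_r_peaks <- function(ecg, refractory = 0.2) {
  stopifnot(inherits(ecg, "waveform_channel"))
  fs <- ecg$fs
  x <- ecg$values
  n <- length(x)
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    return(event_series(numeric(0), kind = "r_peak"))
  }
  nyq <- fs / 2
  bp <- signal::butter(3, c(5, min(15, 0.9 * nyq)) / nyq, type = "pass")
  y <- signal::filtfilt(bp, x)
  d <- c(diff(y), 0)
  sq <- d^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate local maxima of the integrated energy, >= refractory apart
  ref_n <- round(refractory * fs)
  is_max <- c(FALSE, diff(sign(diff(integ))) < 0, FALSE)
  cand <- which(is_max & integ > 0)
  if (!length(cand)) return(event_series(numeric(0), kind = "r_peak"))

  # adaptive signal/noise levels (initialized from the first 2 s)
  init <- integ[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  last <- -Inf
  for (c_i in cand) {
    pk <- integ[c_i]
    if (pk > thr && (c_i - last) >= ref_n) {
      accepted <- c(accepted, c_i)
      spki <- 0.125 * pk + 0.875 * spki
      last <- c_i
    } else if (pk <= thr) {
      npki <- 0.125 * pk + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (!length(accepted)) return(event_series(numeric(0), kind = "r_peak"))

  # refine each detection to the ECG extremum; resolve polarity globally
  half <- as.integer(round(0.1 * fs))
  refine <- function(score) {
    vapply(accepted, function(c_i) {
      lo <- max(1L, as.integer(c_i) - half)
      hi <- min(n, as.integer(c_i) + half)
      lo + which.max(score[lo:hi]) - 1L
    }, integer(1))
  }
  pol <- if (stats::median(x[refine(abs(x))]) < 0) -1 else 1
  ref_idx <- refine(pol * x)
  ref_idx <- sort(unique(ref_idx))
  if (length(ref_idx) > 1L) {
    keep <- c(TRUE, diff(ref_idx) >= ref_n)
    ref_idx <- ref_idx[keep]
  }
  event_series((ref_idx - 1) / fs, kind = "r_peak")
}

#' Correct aberrant RR intervals
#'
#' Automated stand-in for manual tachogram inspection. An interval is flagged
#' when it falls outside `bounds` or deviates from the running median (window
#' `med_win` intervals) by more than `max_dev`. A flagged interval at least
#' 1.6x its local median is treated as one or more missed beats and split
#' into equal plausible sub-intervals (preserving total time); other flagged
#' intervals are replaced by cubic-spline interpolation of interval versus
#' beat time over the clean neighbours. Recordings with more than
#' `max_flagged` of intervals flagged are marked unusable rather than
#' silently corrected.
#'
#' @param rr an `rr_series` with >= 10 intervals.
#' @param bounds plausible interval range, ms.
#' @param max_dev maximal relative deviation from the running median.
#' @param med_win running-median window (odd number of intervals).
#' @param max_flagged maximal tolerated fraction of flagged intervals.
#' @return an `rr_series` with `flags` marking corrected intervals and
#'   attributes `n_corrected`, `usable` and `frac_flagged`.
#' @export
correct_rr_intervals <- function(rr, bounds = c(300, 2000), max_dev = 0.3,
                                 med_win = 11, max_flagged = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  n <- length(iv)
  if (n < 10L) stop_trancehrv("RR correction requires >= 10 intervals")
  med <- stats::runmed(iv, k = min(med_win, n - (1 - n %% 2)), endrule = "median")
  bad <- iv < bounds[1] | iv > bounds[2] | abs(iv - med) / med > max_dev
  frac <- mean(bad)
  if (!any(bad)) {
    out <- rr_series(rr$times, flags = rep(FALSE, n))
    attr(out, "n_corrected") <- 0L
    attr(out, "usable") <- TRUE
    attr(out, "frac_flagged") <- 0
    return(out)
  }
  if (frac > max_flagged) {
    out <- rr_series(rr$times, flags = bad)
    attr(out, "n_corrected") <- 0L
    attr(out, "usable") <- FALSE
    attr(out, "frac_flagged") <- frac
    return(out)
  }

  # rebuild interval-by-interval; long intervals are split (missed beats),
  # the rest interpolated over clean neighbours
  t_mid <- rr$times[-1]  # time at the end of each interval
  good <- !bad
  interp <- function(tq) {
    stats::spline(t_mid[good], iv[good], xout = tq, method = "natural")$y
  }
  new_iv <- list()
  new_flag <- list()
  for (i in seq_len(n)) {
    if (!bad[i]) {
      new_iv[[i]] <- iv[i]
      new_flag[[i]] <- FALSE
    } else if (iv[i] >= 1.6 * med[i]) {
      k <- max(2L, round(iv[i] / med[i]))
      new_iv[[i]] <- rep(iv[i] / k, k)
      new_flag[[i]] <- rep(TRUE, k)
    } else {
      new_iv[[i]] <- interp(t_mid[i])
      new_flag[[i]] <- TRUE
    }
  }
  new_iv <- unlist(new_iv)
  new_flag <- unlist(new_flag)
  new_iv <- pmin(pmax(new_iv, bounds[1]), bounds[2])
  times <- rr$times[1] + c(0, cumsum(new_iv) / 1000)
  out <- rr_series(times, flags = new_flag)
  attr(out, "n_corrected") <- sum(bad)
  attr(out, "usable") <- TRUE
  attr(out, "frac_flagged") <- frac
  out
}

#' Select a contiguous analysis segment of an RR series
#'
#' Extracts exactly `length_s` seconds of beats starting `start_s` seconds
#' into the recording (after trance induction, the published analyses keep
#' the 11 minutes available in every participant). Beat times are re-zeroed
#' to the segment start.
#'
#' Because beats are discrete events, the last beat of a recording falls up
#' to one interval short of the nominal record end; `slack_s` tolerates that
#' shortfall when checking availability.
#'
#' @param rr an `rr_series`.
#' @param length_s segment length, s (default 660 = 11 min).
#' @param start_s segment start offset, s.
#' @param slack_s tolerated shortfall of the beat span versus the nominal
#'   window end, s.
#' @return an `rr_series` restricted to the window.
#' @export
select_segment <- function(rr, length_s = 660, start_s = 0, slack_s = 2) {
  stopifnot(inherits(rr, "rr_series"))
  avail <- rr_span(rr)
  if (avail < start_s + length_s - slack_s) {
    stop_trancehrv(
      "recording too short: %.1f s available, %.1f s required (start %.0f s + %.0f s window)",
      avail, start_s + length_s, start_s, length_s
    )
  }
  t0 <- rr$times[1] + start_s
  keep <- rr$times >= t0 & rr$times <= t0 + length_s
  rr_series(rr$times[keep] - t0, flags = rr$flags[keep[-1] & keep[-length(keep)]])
}

#' Time-domain heart rate variability metrics
#'
#' Direct definitional metrics on an RR series: mean instantaneous heart
#' rate (mean of 60000/RR_i, bpm), mean RR (ms), SDNN (sample SD of RR, ms),
#' RMSSD (root mean square of successive differences, ms) and pNN50
#' (percentage of successive differences exceeding 50 ms).
#'
#' @param rr an `rr_series` (or bare numeric vector of intervals, ms) with
#'   >= 2 intervals.
#' @return named list: `heart_rate`, `rr_mean`, `sdnn`, `rmssd`, `pnn50`.
#' @export
hrv_time_domain <- function(rr) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (length(iv) < 2L) stop_trancehrv("time-domain HRV requires >= 2 intervals")
  d <- diff(iv)
  list(
    heart_rate = mean(60000 / iv),
    rr_mean = mean(iv),
    sdnn = stats::sd(iv),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  )
}

# One-sided Welch power spectral density with Hann window and mean removal
# per segment. Power normalization is density-style: sum(psd) * df equals the
# variance captured by the windowed averages, so band integrals are in
# (signal units)^2.
welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))  # Hann
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / (fs * u)
    sp[2:(nfreq - 1L)] <- 2 * sp[2:(nfreq - 1L)]
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Frequency-domain heart rate variability metrics
#'
#' The irregular tachogram (interval in ms versus beat time) is resampled to
#' a uniform grid by cubic-spline interpolation and its power spectral
#' density estimated by Welch's method (Hann window, mean removal and 50%
#' overlap per segment). Band powers are integrated over the LF and HF bands
#' and normalized by the power in `total_band` (VLF excluded by default);
#' `ln_hf` is the natural log of HF. When HF is exactly zero, `ln_hf` and
#' `lf_hf_ratio` are reported as `NA`, never as infinities.
#'
#' @param rr an `rr_series` spanning >= 120 s.
#' @param interp_fs tachogram resampling rate, Hz.
#' @param welch_seg_s Welch segment length, s.
#' @param overlap Welch segment overlap fraction.
#' @param lf_band,hf_band,total_band frequency bands, Hz (`[lo, hi)`).
#' @return named list: `lf`, `hf`, `total_power` (ms^2), `lfn`, `hfn`,
#'   `ln_hf`, `lf_hf_ratio`.
#' @export
hrv_frequency_domain <- function(rr, interp_fs = 4, welch_seg_s = 120,
                                 overlap = 0.5,
                                 lf_band = c(0.04, 0.15),
                                 hf_band = c(0.15, 0.4),
                                 total_band = c(0.04, 0.4)) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr_span(rr) < 120) stop_trancehrv("spectral HRV requires >= 120 s of beats")
  t_iv <- rr$times[-1]
  grid <- seq(t_iv[1], t_iv[length(t_iv)], by = 1 / interp_fs)
  tach <- stats::spline(t_iv, rr$intervals, xout = grid, method = "fmm")$y
  ps <- welch_psd(tach, interp_fs, nperseg = round(welch_seg_s * interp_fs),
                  overlap = overlap)
  df <- ps$freq[2] - ps$freq[1]
  band_power <- function(band) {
    sum(ps$psd[ps$freq >= band[1] & ps$freq < band[2]]) * df
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  total <- band_power(total_band)
  list(
    lf = lf,
    hf = hf,
    total_power = total,
    lfn = if (total > 0) lf / total else NA_real_,
    hfn = if (total > 0) hf / total else NA_real_,
    ln_hf = if (hf > 0) log(hf) else NA_real_,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_
  )
}

#' Approximate entropy of an interval series
#'
#' Standard ApEn(m, r): Phi_m - Phi_{m+1}, where Phi_m is the mean log
#' fraction of length-m templates lying within Chebyshev distance `r` of each
#' template, self-matches included. Low values indicate a regular,
#' predictable series; the tolerance defaults to the field convention
#' `r = 0.2 * SD` of the series.
#'
#' @param rr an `rr_series` or numeric vector (>= 50 points recommended;
#'   at least `m + 1` required).
#' @param m template length.
#' @param r tolerance in series units; default `0.2 * sd`.
#' @return ApEn, dimensionless scalar.
#' @export
approximate_entropy <- function(rr, m = 2, r = NULL) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (n < m + 2L) stop_trancehrv("ApEn requires at least m + 2 points")
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  phi <- function(mm) {
    nm <- n - mm + 1L
    d <- abs(outer(x[seq_len(nm)], x[seq_len(nm)], "-"))
    if (mm > 1L) {
      for (k in seq_len(mm - 1L)) {
        idx <- seq_len(nm) + k
        d <- pmax(d, abs(outer(x[idx], x[idx], "-")))
      }
    }
    cim <- rowSums(d <= r) / nm
    mean(log(cim))
  }
  phi(m) - phi(m + 1L)
}

#' Heart-rate (mean-RR) correction of spectral HRV metrics
#'
#' Spectral HRV carries a mathematical dependence on the prevailing heart
#' rate. Following the multiplicative correction of Sacha (2014), each raw
#' band power is multiplied by the subject's mean RR interval (expressed in
#' seconds by default, so a mean RR of 800 ms gives multiplier 0.8); log and
#' ratio metrics are recomputed from the corrected powers. Raw values are
#' retained alongside the corrected variants.
#'
#' @param features named list with at least `lf` and `hf` (raw band powers).
#' @param mean_rr subject-level mean RR, ms (> 0).
#' @param unit unit in which mean RR enters the multiplier: `"s"` (default)
#'   or `"ms"`.
#' @return `features` extended with `lf_c`, `hf_c`, `ln_hf_c`,
#'   `lf_hf_ratio_c` and `sacha_multiplier`.
#' @export
sacha_correction <- function(features, mean_rr, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  if (!is.numeric(mean_rr) || mean_rr <= 0) stop_trancehrv("`mean_rr` must be > 0")
  mult <- if (unit == "s") mean_rr / 1000 else mean_rr
  features$sacha_multiplier <- mult
  features$lf_c <- features$lf * mult
  features$hf_c <- features$hf * mult
  features$ln_hf_c <- if (!is.na(features$hf_c) && features$hf_c > 0) {
    log(features$hf_c)
  } else {
    NA_real_
  }
  features$lf_hf_ratio_c <- if (!is.na(features$hf_c) && features$hf_c > 0) {
    features$lf_c / features$hf_c
  } else {
    NA_real_
  }
  features
}

#' Full cardiac feature vector from a raw ECG channel
#'
#' Convenience path chaining [filter_ecg()], [detect_r_peaks()],
#' [correct_rr_intervals()], [select_segment()], the time-domain, spectral
#' and approximate-entropy metrics, and [sacha_correction()]. Returns the
#' 16-element cardiac feature registry plus processing metadata.
#'
#' @param ecg raw ECG `waveform_channel`.
#' @param config an [analysis_config()] list.
#' @param start_s analysis-segment start offset, s (typically the end of the
#'   trance induction period).
#' @return list with `features` (named numeric, 16 metrics), `rr` (the
#'   corrected, segmented `rr_series`), `usable` and `n_corrected`.
#' @export
cardiac_features <- function(ecg, config = analysis_config(), start_s = 0) {
  filt <- filter_ecg(ecg, highpass = config$ecg_highpass,
                     order = config$ecg_order, mains_freq = config$mains_freq)
  peaks <- detect_r_peaks(filt, refractory = config$refractory_s)
  if (length(peaks$times) < 12L) {
    return(list(features = NULL, rr = NULL, usable = FALSE,
                reason = "too_few_beats", n_corrected = NA_integer_))
  }
  rr <- rr_series(peaks$times)
  rr <- correct_rr_intervals(rr, bounds = config$rr_bounds,
                             max_dev = config$rr_max_dev,
                             med_win = config$rr_med_win,
                             max_flagged = config$rr_max_flagged)
  if (!attr(rr, "usable")) {
    return(list(features = NULL, rr = rr, usable = FALSE,
                reason = "excessive_rr_artifacts",
                n_corrected = attr(rr, "n_corrected")))
  }
  rr <- select_segment(rr, length_s = config$segment_s, start_s = start_s)
  td <- hrv_time_domain(rr)
  fd <- hrv_frequency_domain(rr, interp_fs = config$interp_fs,
                             welch_seg_s = config$welch_seg_s,
                             overlap = config$welch_overlap,
                             lf_band = config$lf_band, hf_band = config$hf_band,
                             total_band = config$total_band)
  fd <- sacha_correction(fd, mean_rr = td$rr_mean, unit = config$sacha_unit)
  apen <- approximate_entropy(rr, m = config$apen_m,
                              r = config$apen_r_factor * stats::sd(rr$intervals))
  feats <- c(
    heart_rate = td$heart_rate, rr_mean = td$rr_mean, sdnn = td$sdnn,
    rmssd = td$rmssd, pnn50 = td$pnn50, apen = apen,
    lf = fd$lf, hf = fd$hf, lfn = fd$lfn, hfn = fd$hfn, ln_hf = fd$ln_hf,
    lf_hf_ratio = fd$lf_hf_ratio,
    lf_c = fd$lf_c, hf_c = fd$hf_c, ln_hf_c = fd$ln_hf_c,
    lf_hf_ratio_c = fd$lf_hf_ratio_c
  )
  list(features = feats, rr = rr, usable = TRUE,
       n_corrected = attr(rr, "n_corrected"))
}

#' Names of the cardiac feature registry
#' @return character vector of the 16 cardiac feature names.
#' @export
cardiac_feature_names <- function() {
  c("heart_rate", "rr_mean", "sdnn", "rmssd", "pnn50", "apen",
    "lf", "hf", "lfn", "hfn", "ln_hf", "lf_hf_ratio",
    "lf_c", "hf_c", "ln_hf_c", "lf_hf_ratio_c")
}
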