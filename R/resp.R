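#' Preprocess a respiration-belt channel
#'
#' Removes the linear trend (least squares) and applies a zero-phase
#' fifth-order Butterworth low-pass at 2 Hz, leaving the breathing waveform
#' intact while suppressing movement and sensor noise. Output length equals
#' input length.
#'
#' @param raw a `waveform_channel` (belt), fs > 4 Hz, duration >= 60 s.
#' @param cutoff low-pass cut-off, Hz.
#' @param order Butterworth order.
#' @return filtered `waveform_channel`.
#' @export
preprocess_respiration <- function(raw, cutoff = 2, order = 5) {
  stopifnot(inherits(raw, "waveform_channel"))
  if (raw$fs <= 4) stop_trancehrv("respiration preprocessing requires fs > 4 Hz")
  if (wf_duration(raw) < 60) stop_trancehrv("respiration preprocessing requires >= 60 s")
  tt <- wf_times(raw)
  fit <- stats::lm.fit(cbind(1, tt), raw$values)
  x <- raw$values - fit$fitted.values
  lp <- signal::butter(order, cutoff / (raw$fs / 2), type = "low")
  x <- signal::filtfilt(lp, x)
  waveform_channel(x, raw$fs, role = raw$role)
}

#' Detect breath landmarks in a preprocessed belt signal
#'
#' Zero-crossing-guarded extremum detection: crossings of the signal mean
#' partition the record into putative inspiratory (rising) and expiratory
#' (falling) half-cycles; the maximum of each rising-falling pair is the
#' B peak (inhalation maximum, onset of exhalation) and the preceding
#' minimum the inhale onset. Cycles shorter than `min_period` are merged
#' with their neighbour (the smaller peak is discarded). Detection is
#' invariant to amplitude scaling by construction.
#'
#' @param signal a preprocessed `waveform_channel`.
#' @param min_period minimum breath period, s.
#' @return an object of class `breath_events`: `inhale_onsets` (s),
#'   `peak_times` (s, B peaks), `bb_intervals` (ms), `usable` flag.
#' @export
detect_breaths <- function(signal, min_period = 1.5) {
  stopifnot(inherits(signal, "waveform_channel"))
  x <- signal$values
  fs <- signal$fs
  n <- length(x)
  if (stats::sd(x) < .Machine$double.eps^0.5 * max(1, mean(abs(x)))) {
    return(new_breath_events(numeric(0), numeric(0), usable = FALSE))
  }
  z <- x - mean(x)
  up <- which(z[-n] <= 0 & z[-1] > 0)
  down <- which(z[-n] > 0 & z[-1] <= 0)
  if (length(up) < 2L || length(down) < 1L) {
    return(new_breath_events(numeric(0), numeric(0), usable = FALSE))
  }

  # pair each up-crossing with the next down-crossing: peak between them,
  # trough between previous down-crossing (or record start) and the up-crossing
  peaks <- integer(0)
  troughs <- integer(0)
  prev_down <- 1L
  for (u in up) {
    d <- down[down > u]
    if (!length(d)) break
    d <- d[1]
    lo_t <- max(prev_down, 1L)
    troughs <- c(troughs, lo_t + which.min(x[lo_t:u]) - 1L)
    peaks <- c(peaks, u + which.max(x[u:d]) - 1L)
    prev_down <- d
  }
  if (length(peaks) < 2L) {
    return(new_breath_events(numeric(0), numeric(0), usable = length(peaks) >= 3L))
  }
  # enforce the refractory rule: drop the smaller of two close peaks
  min_n <- round(min_period * fs)
  repeat {
    gaps <- diff(peaks)
    short <- which(gaps < min_n)
    if (!length(short)) break
    i <- short[1]
    drop <- if (x[peaks[i]] >= x[peaks[i + 1]]) i + 1L else i
    peaks <- peaks[-drop]
    # remove the trough between the merged peaks
    if (drop <= length(troughs) && drop > 1L) troughs <- troughs[-drop]
  }
  # one trough (inhale onset) before each surviving peak
  tr_keep <- vapply(peaks, function(p) {
    cand <- troughs[troughs < p]
    if (length(cand)) cand[length(cand)] else NA_integer_
  }, integer(1))
  ok <- !is.na(tr_keep) & !duplicated(tr_keep)
  peaks <- peaks[ok]
  tr_keep <- tr_keep[ok]
  usable <- length(peaks) >= 3L
  new_breath_events((tr_keep - 1) / fs, (peaks - 1) / fs, usable = usable)
}

new_breath_events <- function(inhale_onsets, peak_times, usable = TRUE,
                              flags = NULL, n_corrected = 0L) {
  bb <- diff(peak_times) * 1000
  structure(
    list(inhale_onsets = as.numeric(inhale_onsets),
         peak_times = as.numeric(peak_times),
         bb_intervals = bb,
         flags = flags %||% rep(FALSE, length(bb)),
         usable = usable,
         n_corrected = n_corrected),
    class = "breath_events"
  )
}

#' @export
print.breath_events <- function(x, ...) {
  cat(sprintf(
    "<breath_events> %d breaths, mean BB %.0f ms, usable=%s\n",
    length(x$peak_times),
    if (length(x$bb_intervals)) mean(x$bb_intervals) else NA_real_,
    x$usable
  ))
  invisible(x)
}

#' Correct aberrant breath-to-breath intervals
#'
#' Same rule family as the cardiac correction with respiratory bounds: a BB
#' interval is flagged when outside `bounds` (1.5-20 s by default) or
#' deviating from the running median by more than
#' `max(max_dev * median, mad_mult * MAD)`. The MAD guard keeps the rule
#' aimed at detection artifacts: healthy breathing is far more variable than
#' a cardiac tachogram (breath-to-breath SDs of 1-3 s on 4 s breaths are
#' physiological), and a fixed relative threshold would flag — and bias —
#' genuine variability. A flagged interval below 60% of its local median is
#' treated as a doubled (spurious) peak and merged; other flagged intervals
#' are replaced by spline interpolation over clean neighbours. More than
#' `max_flagged` flagged intervals marks the recording unusable.
#'
#' @param events a `breath_events` with >= 3 intervals.
#' @param bounds plausible BB range, ms.
#' @param max_dev maximal relative deviation from the running median.
#' @param mad_mult robust-spread multiplier of the deviation guard.
#' @param med_win running-median window.
#' @param max_flagged maximal tolerated flagged fraction.
#' @return a corrected `breath_events` (fields `flags`, `n_corrected`,
#'   `usable` updated).
#' @export
correct_bb_intervals <- function(events, bounds = c(1500, 20000),
                                 max_dev = 0.4, mad_mult = 3.5,
                                 med_win = 11, max_flagged = 0.2) {
  stopifnot(inherits(events, "breath_events"))
  bb <- events$bb_intervals
  n <- length(bb)
  if (n < 3L) stop_trancehrv("BB correction requires >= 3 intervals")
  med <- stats::runmed(bb, k = min(med_win, n - (1 - n %% 2)), endrule = "median")
  guard <- pmax(max_dev * med, mad_mult * stats::mad(bb))
  bad <- bb < bounds[1] | bb > bounds[2] | abs(bb - med) > guard
  frac <- mean(bad)
  if (!any(bad)) {
    events$flags <- rep(FALSE, n)
    events$n_corrected <- 0L
    return(events)
  }
  if (frac > max_flagged) {
    events$flags <- bad
    events$usable <- FALSE
    events$n_corrected <- 0L
    return(events)
  }
  peaks <- events$peak_times
  onsets <- events$inhale_onsets
  n_fixed <- 0L
  # merge doubled breaths first: drop the peak that ends a too-short interval,
  # one at a time (a single spurious peak shortens two adjacent intervals)
  repeat {
    nn <- length(peaks)
    bb <- diff(peaks) * 1000
    med <- stats::runmed(bb, k = min(med_win, nn - 1L - (1 - (nn - 1L) %% 2)),
                         endrule = "median")
    guard <- pmax(max_dev * med, mad_mult * stats::mad(bb))
    bad <- bb < bounds[1] | bb > bounds[2] | abs(bb - med) > guard
    short <- which(bad & bb < 0.6 * med)
    if (!length(short) || nn <= 3L) break
    drop_peak <- min(short[1] + 1L, nn)
    peaks <- peaks[-drop_peak]
    onsets <- onsets[-drop_peak]
    n_fixed <- n_fixed + 1L
  }
  flags <- bad
  if (any(bad) && any(!bad)) {
    t_mid <- peaks[-1]
    bb[bad] <- stats::spline(t_mid[!bad], bb[!bad], xout = t_mid[bad],
                             method = "natural")$y
    bb <- pmin(pmax(bb, bounds[1]), bounds[2])
  }
  out <- new_breath_events(onsets, peaks, usable = TRUE,
                           flags = flags, n_corrected = n_fixed + sum(flags))
  out$bb_intervals <- bb
  out
}

#' Respiratory feature vector from breath events
#'
#' Computes the five respiratory-variability features of one belt channel:
#' mean respiratory rate (breaths/min, 60000 / mean BB), mean amplitude
#' (per-breath peak minus preceding-trough excursion, channel units),
#' phase-duration ratio (mean inspiratory over mean expiratory duration,
#' inspiration defined trough-to-peak and expiration peak-to-next-trough),
#' SDBB (SD of BB intervals, ms) and RMSSD-BB (root mean square of
#' successive BB differences, ms).
#'
#' @param events a corrected `breath_events`.
#' @param signal the matching preprocessed `waveform_channel` (used for
#'   amplitude).
#' @return named list: `resp_rate`, `amplitude`, `phase_ratio`, `sdbb`,
#'   `rmssd_bb`, `n_breaths`.
#' @export
resp_features <- function(events, signal) {
  stopifnot(inherits(events, "breath_events"))
  if (!events$usable || length(events$peak_times) < 3L) {
    stop_trancehrv("respiratory features require a usable series with >= 3 breaths")
  }
  bb <- events$bb_intervals
  peaks <- events$peak_times
  onsets <- events$inhale_onsets
  idx <- function(t) pmin(pmax(round(t * signal$fs) + 1L, 1L), length(signal$values))
  amp <- mean(signal$values[idx(peaks)] - signal$values[idx(onsets)])
  insp <- peaks - onsets
  nb <- length(peaks)
  expd <- onsets[-1] - peaks[-nb]
  expd <- expd[expd > 0]
  d <- diff(bb)
  list(
    resp_rate = 60000 / mean(bb),
    amplitude = amp,
    phase_ratio = mean(insp) / mean(expd),
    sdbb = stats::sd(bb),
    rmssd_bb = if (length(d)) sqrt(mean(d^2)) else 0,
    n_breaths = nb
  )
}

#' Respiratory features for both belts of a recording
#'
#' Runs the identical preprocess / detect / correct / feature path on the
#' thoracic and abdominal channels independently and assembles the
#' 11-element respiratory feature registry: the five per-belt features for
#' each belt plus the belt-averaged respiratory rate.
#'
#' @param thoracic,abdominal raw belt `waveform_channel`s.
#' @param config an [analysis_config()] list.
#' @return list with `features` (named numeric, 11 metrics), `usable`, and
#'   per-belt event objects.
#' @export
respiration_features <- function(thoracic, abdominal, config = analysis_config()) {
  run_belt <- function(wave) {
    pre <- preprocess_respiration(wave, cutoff = config$resp_lowpass,
                                  order = config$resp_order)
    ev <- detect_breaths(pre, min_period = config$min_breath_period)
    if (!ev$usable) return(list(usable = FALSE, events = ev))
    ev <- correct_bb_intervals(ev, bounds = config$bb_bounds,
                               max_dev = config$bb_max_dev,
                               mad_mult = config$bb_mad_mult,
                               max_flagged = config$bb_max_flagged)
    if (!ev$usable) return(list(usable = FALSE, events = ev))
    list(usable = TRUE, events = ev, features = resp_features(ev, pre))
  }
  th <- run_belt(thoracic)
  ab <- run_belt(abdominal)
  if (!th$usable || !ab$usable) {
    return(list(features = NULL, usable = FALSE,
                reason = "unusable_respiration", thoracic = th, abdominal = ab))
  }
  f <- c(
    thor_rate = th$features$resp_rate,
    thor_amplitude = th$features$amplitude,
    thor_phase_ratio = th$features$phase_ratio,
    thor_sdbb = th$features$sdbb,
    thor_rmssd_bb = th$features$rmssd_bb,
    abdo_rate = ab$features$resp_rate,
    abdo_amplitude = ab$features$amplitude,
    abdo_phase_ratio = ab$features$phase_ratio,
    abdo_sdbb = ab$features$sdbb,
    abdo_rmssd_bb = ab$features$rmssd_bb,
    resp_rate_mean = (th$features$resp_rate + ab$features$resp_rate) / 2
  )
  list(features = f, usable = TRUE, thoracic = th, abdominal = ab)
}

#' Names of the respiratory feature registry
#' @return character vector of the 11 respiratory feature names.
#' @export
resp_feature_names <- function() {
  c("thor_rate", "thor_amplitude", "thor_phase_ratio", "thor_sdbb",
    "thor_rmssd_bb", "abdo_rate", "abdo_amplitude", "abdo_phase_ratio",
    "abdo_sdbb", "abdo_rmssd_bb", "resp_rate_mean")
}
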