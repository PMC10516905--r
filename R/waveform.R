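#' Uniformly sampled physiological waveform
#'
#' Light container for one channel of a polygraph recording: a numeric sample
#' vector, its sampling rate, and the channel role (`"ecg"`, `"thoracic"`,
#' `"abdominal"` or `"generic"`). Sample `i` is taken at time `(i - 1) / fs`
#' seconds from recording onset.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param role channel role label.
#' @return an object of class `waveform_channel`.
#' @export
waveform_channel <- function(values, fs,
                             role = c("generic", "ecg", "thoracic", "abdominal")) {
  role <- match.arg(role)
  if (!is.numeric(values) || length(values) < 2L) {
    stop_trancehrv("a waveform needs at least two numeric samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_trancehrv("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs), role = role),
    class = "waveform_channel"
  )
}

#' @export
print.waveform_channel <- function(x, ...) {
  cat(sprintf(
    "<waveform_channel> role=%s fs=%g Hz n=%d (%.1f s)\n",
    x$role, x$fs, length(x$values), wf_duration(x)
  ))
  invisible(x)
}

# Duration in seconds (n samples at fs Hz cover n/fs seconds).
wf_duration <- function(wave) length(wave$values) / wave$fs

wf_times <- function(wave) (seq_along(wave$values) - 1) / wave$fs

#' Ordered physiological event times
#'
#' Container for a strictly increasing sequence of event times in seconds
#' (R peaks or breath landmarks) with the derived inter-event intervals in
#' milliseconds.
#'
#' @param times numeric vector of event times in seconds, strictly increasing.
#' @param kind event kind label, e.g. `"r_peak"` or `"b_peak"`.
#' @return an object of class `event_series` with fields `times` (s),
#'   `intervals` (ms) and `kind`.
#' @export
event_series <- function(times, kind = "event") {
  times <- as.numeric(times)
  if (length(times) && any(!is.finite(times))) {
    stop_trancehrv("event times must be finite")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_trancehrv("event times must be strictly increasing")
  }
  structure(
    list(times = times, intervals = diff(times) * 1000, kind = kind),
    class = "event_series"
  )
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf(
    "<event_series> kind=%s n=%d events, mean interval %.1f ms\n",
    x$kind, length(x$times),
    if (length(x$intervals)) mean(x$intervals) else NA_real_
  ))
  invisible(x)
}

#' RR interval series
#'
#' Beat-to-beat interval container: beat times in seconds, the intervals
#' between successive beats in milliseconds, and a per-interval flag marking
#' intervals that were replaced by the artifact-correction rule.
#'
#' @param beat_times beat (R-peak) times in seconds, strictly increasing.
#' @param flags optional logical vector, one element per interval, marking
#'   corrected intervals.
#' @return an object of class `rr_series` with fields `times` (s),
#'   `intervals` (ms), `flags`, and attributes set by the correction step.
#' @export
rr_series <- function(beat_times, flags = NULL) {
  ev <- event_series(beat_times, kind = "r_peak")
  n_int <- length(ev$intervals)
  if (n_int && any(ev$intervals <= 0)) {
    stop_trancehrv("all RR intervals must be positive")
  }
  if (is.null(flags)) flags <- rep(FALSE, n_int)
  if (length(flags) != n_int) {
    stop_trancehrv("`flags` must have one element per interval")
  }
  structure(
    list(times = ev$times, intervals = ev$intervals, flags = as.logical(flags)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d beats over %.1f s, mean RR %.1f ms, %d corrected\n",
    length(x$times), diff(range(x$times)),
    mean(x$intervals), sum(x$flags)
  ))
  invisible(x)
}

# Span of the beat-time series in seconds.
rr_span <- function(rr) if (length(rr$times) < 2L) 0 else diff(range(rr$times))
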