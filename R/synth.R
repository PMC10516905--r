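#' Generative parameters for one experimental condition
#'
#' A `condition_profile` fixes the autonomic ground truth for one condition of
#' the synthetic cohort: mean RR interval, depths of the low-frequency
#' (baroreflex-band) and high-frequency (respiratory-band) sinusoidal RR
#' modulations, residual beat-to-beat noise, and the respiratory pattern
#' (rate, belt amplitude, inspiratory/expiratory duration ratio, breath-period
#' jitter). `hr_entropy_mix` sets the fraction of the residual RR noise that
#' is broadband (white) rather than slow (AR(1)); more broadband noise yields
#' a more irregular, higher-entropy tachogram.
#'
#' @param name condition label.
#' @param mean_rr mean RR interval, ms (300-2000).
#' @param lf_depth amplitude of the 0.04-0.15 Hz RR modulation, ms.
#' @param hf_depth amplitude of the respiratory-band RR modulation, ms.
#' @param rr_noise_sd SD of residual beat-to-beat RR noise, ms.
#' @param resp_rate respiratory rate, breaths/min.
#' @param resp_amp peak-to-trough belt excursion, arbitrary units.
#' @param ie_ratio inspiratory over expiratory duration ratio.
#' @param bb_jitter_sd SD of breath-period jitter, ms.
#' @param hr_entropy_mix fraction in `[0, 1]` of broadband RR noise.
#' @param lf_freq generator frequency of the LF modulation, Hz.
#' @param hf_freq generator frequency of the HF modulation, Hz; defaults to
#'   the respiratory frequency `resp_rate / 60`.
#' @return an object of class `condition_profile`.
#' @export
condition_profile <- function(name, mean_rr,
                              lf_depth = 0, hf_depth = 0, rr_noise_sd = 0,
                              resp_rate = 15, resp_amp = 200, ie_ratio = 0.8,
                              bb_jitter_sd = 0, hr_entropy_mix = 0.5,
                              lf_freq = 0.1, hf_freq = NULL) {
  p <- structure(
    list(
      name = as.character(name), mean_rr = mean_rr,
      lf_depth = lf_depth, hf_depth = hf_depth, rr_noise_sd = rr_noise_sd,
      resp_rate = resp_rate, resp_amp = resp_amp, ie_ratio = ie_ratio,
      bb_jitter_sd = bb_jitter_sd, hr_entropy_mix = hr_entropy_mix,
      lf_freq = lf_freq, hf_freq = hf_freq %||% (resp_rate / 60)
    ),
    class = "condition_profile"
  )
  validate_profile(p)
  p
}

#' Validate a condition profile
#'
#' Enforces the physiological envelope of the generator: RR mean within
#' 300-2000 ms, positive respiratory rate and phase ratio, non-negative
#' modulation depths, and total modulation small enough
#' (`lf_depth + hf_depth + rr_noise_sd < mean_rr / 2`) that generated
#' intervals cannot plausibly go non-positive.
#'
#' @param p a `condition_profile`.
#' @return `p`, invisibly; stops with a diagnostic on violation.
#' @export
validate_profile <- function(p) {
  if (!inherits(p, "condition_profile")) {
    stop_trancehrv("expected a `condition_profile`")
  }
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("mean_rr", "lf_depth", "hf_depth", "rr_noise_sd", "resp_rate",
              "resp_amp", "ie_ratio", "bb_jitter_sd", "hr_entropy_mix",
              "lf_freq", "hf_freq")) {
    if (!num_ok(p[[f]])) stop_trancehrv("profile '%s': field `%s` must be a finite number", p$name, f)
  }
  if (p$mean_rr < 300 || p$mean_rr > 2000) {
    stop_trancehrv("profile '%s': mean_rr %.1f ms outside [300, 2000]", p$name, p$mean_rr)
  }
  if (p$resp_rate <= 0) stop_trancehrv("profile '%s': resp_rate must be > 0", p$name)
  if (p$ie_ratio <= 0) stop_trancehrv("profile '%s': ie_ratio must be > 0", p$name)
  for (f in c("lf_depth", "hf_depth", "rr_noise_sd", "resp_amp", "bb_jitter_sd")) {
    if (p[[f]] < 0) stop_trancehrv("profile '%s': `%s` must be >= 0", p$name, f)
  }
  if (p$hr_entropy_mix < 0 || p$hr_entropy_mix > 1) {
    stop_trancehrv("profile '%s': hr_entropy_mix must lie in [0, 1]", p$name)
  }
  if (p$lf_depth + p$hf_depth + p$rr_noise_sd >= p$mean_rr / 2) {
    stop_trancehrv(
      "profile '%s': lf_depth + hf_depth + rr_noise_sd must stay below mean_rr/2",
      p$name
    )
  }
  invisible(p)
}

#' Default condition profiles for the three-condition study design
#'
#' Profiles for Rest, Imag (imagination) and SICT (self-induced cognitive
#' trance) whose group-level targets follow the published autonomic pattern:
#' higher heart rate (Rest ~69.25 bpm vs SICT ~81.07 bpm), higher overall RR
#' variability but reduced respiratory-band (HF) modulation and a more
#' regular (lower-entropy) tachogram during trance, together with larger
#' breathing amplitude, a raised inspiratory/expiratory phase ratio and much
#' larger breath-to-breath jitter. The Imag profile is generatively identical
#' to Rest: imagination without trance induction showed no autonomic shift,
#' so any Rest-vs-Imag decoding on this cohort estimates the null.
#'
#' @return named list of three `condition_profile` objects
#'   (`Rest`, `Imag`, `SICT`).
#' @export
default_condition_profiles <- function() {
  rest <- condition_profile(
    "Rest",
    mean_rr = 60000 / 69.25,  # ~866 ms -> 69.25 bpm
    lf_depth = 45, hf_depth = 28, rr_noise_sd = 24,
    resp_rate = 15.41, resp_amp = 210, ie_ratio = 0.74,
    bb_jitter_sd = 1300, hr_entropy_mix = 0.50
  )
  imag <- rest
  imag$name <- "Imag"
  sict <- condition_profile(
    "SICT",
    mean_rr = 60000 / 81.07,  # ~740 ms -> 81.07 bpm
    lf_depth = 70, hf_depth = 11, rr_noise_sd = 30,
    resp_rate = 14.96, resp_amp = 375, ie_ratio = 1.04,
    bb_jitter_sd = 2600, hr_entropy_mix = 0.05
  )
  list(Rest = rest, Imag = imag, SICT = sict)
}

#' Generate a synthetic RR interval series
#'
#' Direct interval modulation: each interval is the profile mean plus an LF
#' sinusoid, an HF (respiratory-frequency) sinusoid, and residual noise that
#' mixes a slow AR(1) component with broadband white noise in proportion
#' `hr_entropy_mix`. Beat `k + 1` occurs `RR_k` after beat `k`; generation
#' stops at `duration`. Sinusoid phases are drawn once per call from `seed`,
#' so identical `(profile, duration, seed)` give bit-identical output.
#'
#' @param profile a `condition_profile`.
#' @param duration recording duration, s (>= 120).
#' @param seed integer seed.
#' @return an `event_series` of beat times (kind `"r_peak"`).
#' @export
generate_rr_series <- function(profile, duration, seed = 1L) {
  validate_profile(profile)
  if (duration < 120) stop_trancehrv("duration must be >= 120 s")
  with_seed(seed, {
    n_max <- ceiling(duration * 1000 / max(profile$mean_rr / 2, 300)) + 2L
    phi_lf <- stats::runif(1, 0, 2 * pi)
    phi_hf <- stats::runif(1, 0, 2 * pi)
    white <- stats::rnorm(n_max)
    innov <- stats::rnorm(n_max)
    rho <- 0.97  # slow, predictable residual; broadband mix carries the entropy
    ar1 <- as.numeric(stats::filter(innov * sqrt(1 - rho^2), rho,
                                    method = "recursive"))
    mix <- profile$hr_entropy_mix
    noise <- profile$rr_noise_sd * (sqrt(1 - mix) * ar1 + sqrt(mix) * white)

    times <- numeric(n_max)
    t <- 0
    k <- 0L
    while (t <= duration && k < n_max) {
      k <- k + 1L
      times[k] <- t
      rr <- profile$mean_rr +
        profile$lf_depth * sin(2 * pi * profile$lf_freq * t + phi_lf) +
        profile$hf_depth * sin(2 * pi * profile$hf_freq * t + phi_hf) +
        noise[k]
      rr <- max(rr, 300)  # hard physiological floor; unreachable for valid profiles
      t <- t + rr / 1000
    }
    event_series(times[seq_len(k)], kind = "r_peak")
  })
}

#' Render a synthetic ECG waveform from beat times
#'
#' Places a fixed biphasic QRS-like kernel (Q and S dips flanking a dominant
#' R deflection, Gaussian lobes) at each beat time on a uniform sampling
#' grid. Morphological realism (P/T waves, ectopy) is out of scope; the
#' waveform exists so the detection path has a raw signal whose true R times
#' are known exactly. Optional contaminants exercise the preprocessing
#' filters: low-frequency baseline wander and a mains (powerline) sinusoid.
#'
#' @param r_times strictly increasing R-peak times, s.
#' @param fs sampling rate, Hz (>= 100).
#' @param duration waveform duration, s; default covers the last beat + 1 s.
#' @param baseline_wander logical; add a 0.25 Hz drift of amplitude 0.2.
#' @param powerline logical; add a mains sinusoid of amplitude 0.1.
#' @param mains_freq mains frequency for the contaminant, Hz.
#' @param polarity `1` for upright R peaks, `-1` for inverted leads.
#' @return a `waveform_channel` with role `"ecg"`.
#' @export
synthesize_ecg <- function(r_times, fs = 250, duration = NULL,
                           baseline_wander = FALSE, powerline = FALSE,
                           mains_freq = 50, polarity = 1) {
  if (inherits(r_times, "event_series")) r_times <- r_times$times
  r_times <- as.numeric(r_times)
  if (!length(r_times)) stop_trancehrv("`r_times` must contain at least one beat")
  if (any(diff(r_times) <= 0)) stop_trancehrv("`r_times` must be strictly increasing")
  if (fs < 100) stop_trancehrv("`fs` must be >= 100 Hz for ECG synthesis")
  duration <- duration %||% (max(r_times) + 1)

  n <- ceiling(duration * fs)
  x <- numeric(n)
  # QRS kernel: R lobe sigma 12 ms, Q/S dips at -28/+32 ms
  half <- round(0.08 * fs)
  off <- (-half):half
  for (rt in r_times) {
    c_idx <- round(rt * fs) + 1L  # sample 1 is t = 0
    idx <- c_idx + off
    keep <- idx >= 1L & idx <= n
    tt <- (idx[keep] - 1) / fs - rt
    kern <- exp(-0.5 * (tt / 0.012)^2) -
      0.18 * exp(-0.5 * ((tt + 0.028) / 0.010)^2) -
      0.28 * exp(-0.5 * ((tt - 0.032) / 0.010)^2)
    x[idx[keep]] <- x[idx[keep]] + kern
  }
  tgrid <- (seq_len(n) - 1) / fs
  if (baseline_wander) x <- x + 0.2 * sin(2 * pi * 0.25 * tgrid)
  if (powerline) x <- x + 0.1 * sin(2 * pi * mains_freq * tgrid)
  waveform_channel(polarity * x, fs, role = "ecg")
}

#' Render a synthetic respiration-belt waveform
#'
#' Each breath is a piecewise-asymmetric raised cosine: the signal rises from
#' trough to peak over the inspiratory phase and falls back over the
#' expiratory phase, with the two phase durations in exact ratio `ie_ratio`.
#' Breath periods are `60 / resp_rate` seconds plus Gaussian jitter of SD
#' `bb_jitter_sd` ms, truncated to the physiological range `[1.5, 20]` s.
#' Per-breath amplitude varies mildly (5% CV) around `resp_amp` scaled by
#' `amp_scale`; amplitude enters the rendering linearly, so scaling the
#' profile amplitude scales the waveform exactly. A small DC offset and
#' linear drift are added so the detrending step of the analysis path is
#' exercised. Breath timing depends only on `(profile, duration, seed)`:
#' rendering twice with different `amp_scale` (e.g. thoracic vs abdominal
#' belt) yields channels that share identical ground-truth breath times.
#'
#' @param profile a `condition_profile`.
#' @param duration recording duration, s (>= 120).
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param amp_scale multiplicative amplitude scale for this belt.
#' @return list with `wave` (a `waveform_channel`), `trough_times`,
#'   `peak_times` (exhalation onsets, the B peaks) and `ie_ratio` used.
#' @export
synthesize_respiration <- function(profile, duration, seed = 1L, fs = 250,
                                   amp_scale = 1) {
  validate_profile(profile)
  if (duration < 120) stop_trancehrv("duration must be >= 120 s")
  with_seed(seed, {
    mean_period <- 60 / profile$resp_rate
    ie <- profile$ie_ratio
    n_max <- ceiling(duration / 1.5) + 3L
    # B-peak (exhalation onset) times are the jittered anchor sequence, so
    # the SD of true BB intervals equals bb_jitter_sd by construction
    gaps <- pmin(pmax(stats::rnorm(n_max, mean_period, profile$bb_jitter_sd / 1000),
                      1.5), 20)
    amps <- profile$resp_amp * pmax(1 + 0.05 * stats::rnorm(n_max), 0.2)
    peaks <- mean_period * ie / (1 + ie) + cumsum(c(0, gaps))
    n_br <- max(which(peaks <= duration + mean_period))
    peaks <- peaks[seq_len(n_br)]
    amps <- amps[seq_len(n_br)]
    # each inter-peak gap splits into expiration then the next inspiration in
    # ratio 1 : ie; per-breath I/E is exact at zero jitter and exact in the
    # mean under jitter
    troughs <- c(0, peaks[-n_br] + gaps[seq_len(n_br - 1L)] / (1 + ie))

    bounds <- as.vector(rbind(troughs, peaks))  # t1 p1 t2 p2 ...
    n <- ceiling(duration * fs)
    tt <- (seq_len(n) - 1) / fs
    seg <- findInterval(tt, bounds, rightmost.closed = FALSE)
    seg[seg < 1L] <- 1L
    seg[seg > 2L * n_br - 1L] <- 2L * n_br - 1L
    rising <- seg %% 2L == 1L
    br <- (seg + 1L) %/% 2L
    lo <- bounds[seg]
    hi <- bounds[pmin(seg + 1L, length(bounds))]
    frac <- pmin(pmax((tt - lo) / pmax(hi - lo, 1e-9), 0), 1)
    ph <- ifelse(rising, 0.5 * (1 - cos(pi * frac)), 0.5 * (1 + cos(pi * frac)))
    x <- amp_scale * amps[br] * ph + 0.05 * profile$resp_amp +
      0.002 * profile$resp_amp * tt

    keep_peak <- peaks <= duration
    list(
      wave = waveform_channel(x, fs, role = "generic"),
      trough_times = troughs[troughs <= duration],
      peak_times = peaks[keep_peak],
      ie_ratio = ie
    )
  })
}

#' Generate a synthetic cohort of raw recordings with ground truth
#'
#' Builds `n_subjects` subjects, each recorded under every condition profile.
#' Subject-level physiology is a set of multiplicative log-normal random
#' effects (on mean RR, modulation depths, respiratory rate, amplitude,
#' phase ratio and breath jitter) shared across that subject's conditions, so
#' the within-subject pairing of the study design is preserved; a small
#' independent per-recording jitter (3% CV) is added on top. With
#' `center_effects = TRUE` (default) each random-effect field is rescaled to
#' unit geometric mean across subjects, so realized cohort-level means track
#' the profile targets even at small n — the cohort is calibrated to, not
#' merely centered on, the condition targets.
#'
#' Each recording comprises one ECG channel and two respiration belts
#' (thoracic, and abdominal at 0.85 relative gain) sharing one set of true
#' breath times. All child seeds derive deterministically from `master_seed`.
#' SICT recordings carry a trance-intensity self-rating emulating the
#' published distribution (mean ~6.7, range 3-10).
#'
#' @param n_subjects number of subjects (>= 0); default 26.
#' @param profiles named list of `condition_profile`s; default
#'   [default_condition_profiles()].
#' @param duration_s recording duration per condition, s.
#' @param fs sampling rate, Hz.
#' @param master_seed integer seed for the whole cohort.
#' @param subject_ids optional character vector of unique subject ids.
#' @param center_effects logical; rescale random effects to unit geometric
#'   mean across the cohort.
#' @param waveforms logical; if `FALSE`, skip waveform rendering and return
#'   ground-truth event times only (fast path for event-level studies).
#' @return an object of class `synthetic_cohort`: list with `recordings`
#'   (one element per subject x condition: channels, truth, realized
#'   profile, seed) and `manifest` (data frame: subject_id, condition, fs,
#'   duration_s, induction_end_s, trance_intensity, seed).
#' @export
generate_cohort <- function(n_subjects = 26,
                            profiles = default_condition_profiles(),
                            duration_s = 720, fs = 250, master_seed = 1L,
                            subject_ids = NULL, center_effects = TRUE,
                            waveforms = TRUE) {
  if (n_subjects < 0) stop_trancehrv("`n_subjects` must be >= 0")
  for (p in profiles) validate_profile(p)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  }
  if (anyDuplicated(subject_ids)) stop_trancehrv("duplicate subject_id in cohort")
  if (length(subject_ids) != n_subjects) {
    stop_trancehrv("`subject_ids` must have length `n_subjects`")
  }

  re_fields <- c(mean_rr = 0.11, lf_depth = 0.20, hf_depth = 0.25,
                 rr_noise_sd = 0.15, resp_rate = 0.14, resp_amp = 0.45,
                 ie_ratio = 0.22, bb_jitter_sd = 0.30)
  offsets <- with_seed(child_seed(master_seed, 1L), {
    m <- matrix(0, n_subjects, length(re_fields),
                dimnames = list(subject_ids, names(re_fields)))
    for (j in seq_along(re_fields)) {
      e <- stats::rnorm(n_subjects, 0, re_fields[j])
      if (center_effects && n_subjects > 0) e <- e - mean(e)
      m[, j] <- exp(e)
    }
    m
  })
  intensities <- with_seed(child_seed(master_seed, 2L), {
    pmin(pmax(round(stats::rnorm(max(n_subjects, 1L), 6.69, 1.89)), 3), 10)
  })

  recordings <- list()
  manifest <- list()
  cond_names <- names(profiles)
  for (i in seq_len(n_subjects)) {
    for (ci in seq_along(profiles)) {
      prof <- profiles[[ci]]
      seed_rec <- child_seed(master_seed, 10L + i, ci)
      realized <- prof
      jitter <- with_seed(child_seed(seed_rec, 99L),
                          exp(stats::rnorm(length(re_fields), 0, 0.03)))
      for (j in seq_along(re_fields)) {
        f <- names(re_fields)[j]
        realized[[f]] <- prof[[f]] * offsets[i, j] * jitter[j]
      }
      realized$mean_rr <- min(max(realized$mean_rr, 310), 1990)
      realized$hf_freq <- realized$resp_rate / 60
      validate_profile(realized)

      rr <- generate_rr_series(realized, duration_s, seed = child_seed(seed_rec, 1L))
      resp_seed <- child_seed(seed_rec, 2L)
      rec <- list(
        subject_id = subject_ids[i],
        condition = prof$name,
        truth_r_times = rr$times,
        truth_rr_ms = rr$intervals,
        profile_used = realized,
        seed = seed_rec,
        fs = fs,
        duration_s = duration_s
      )
      if (waveforms) {
        thor <- synthesize_respiration(realized, duration_s, seed = resp_seed,
                                       fs = fs, amp_scale = 1)
        abdo <- synthesize_respiration(realized, duration_s, seed = resp_seed,
                                       fs = fs, amp_scale = 0.85)
        thor$wave$role <- "thoracic"
        abdo$wave$role <- "abdominal"
        rec$ecg <- synthesize_ecg(rr$times, fs = fs, duration = duration_s)
        rec$thoracic <- thor$wave
        rec$abdominal <- abdo$wave
        rec$truth_breath_times <- thor$peak_times
        rec$truth_trough_times <- thor$trough_times
      } else {
        thor <- synthesize_respiration(realized, duration_s, seed = resp_seed,
                                       fs = 10, amp_scale = 1)
        rec$truth_breath_times <- thor$peak_times
        rec$truth_trough_times <- thor$trough_times
      }
      recordings[[length(recordings) + 1L]] <- rec
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = subject_ids[i],
        condition = prof$name,
        fs = fs,
        duration_s = duration_s,
        induction_end_s = 60,
        trance_intensity = if (prof$name == "SICT") intensities[i] else NA_real_,
        seed = seed_rec,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else data.frame(
    subject_id = character(), condition = character(), fs = numeric(),
    duration_s = numeric(), induction_end_s = numeric(),
    trance_intensity = numeric(), seed = integer(), stringsAsFactors = FALSE
  )
  structure(
    list(recordings = recordings, manifest = manifest,
         conditions = cond_names, master_seed = master_seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d recordings (%d subjects x %s), master_seed=%d\n",
    length(x$recordings),
    length(unique(x$manifest$subject_id)),
    paste(x$conditions, collapse = "/"),
    x$master_seed
  ))
  invisible(x)
}
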