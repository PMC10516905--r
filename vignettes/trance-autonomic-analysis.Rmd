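---
title: "Cardio-respiratory variability analysis and condition decoding with trancehrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardio-respiratory variability analysis and condition decoding with trancehrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trancehrv)
```

## The analysis problem

Self-induced cognitive trance (SICT) is a volitional non-ordinary state of
consciousness; studies of its autonomic signature record ECG and two
respiration belts (thoracic, abdominal) while participants rest, imagine a
previous trance without entering it (Imag), and induce an actual trance
(SICT). The scientific questions are (i) which heart rate variability (HRV)
and respiratory rate variability (RRV) features change during trance, (ii)
whether single features suffice to decode the condition of an observation,
and (iii) how phasic (task-minus-rest) vagal reactivity relates to tonic
(resting) vagal tone.

`trancehrv` implements that full analysis as a tested pipeline:

1. **Cardiac path** — ECG high-pass (0.5 Hz, order 5, zero phase) and mains
   notch; R-peak detection; automated RR artifact correction; selection of
   an 11-minute analysis segment; time-domain metrics (heart rate, mean RR,
   SDNN, RMSSD, pNN50), Welch spectral metrics (LF, HF, normalized powers,
   lnHF, LF/HF) and approximate entropy; mean-RR (Sacha) correction of the
   spectral metrics.
2. **Respiratory path** — linear detrend and 2 Hz order-5 low-pass; breath
   landmark detection (B peak = inhalation maximum = exhalation onset);
   BB-interval correction; rate, amplitude, inspiratory/expiratory
   phase-duration ratio, SDBB and RMSSD-BB per belt.
3. **Inference** — per-feature two-class linear discriminant decoding under
   leave-one-subject-out (LOSO) cross-validation; permutation null
   (n = 1000) with maximum statistics across the 27-feature registry for
   familywise error control; phasic/tonic difference analysis with Spearman
   correlation; Pearson dependence checks of HRV on heart rate and
   respiratory rate.
4. **Synthetic cohort generator** — because the study's human recordings are
   not publicly deposited, a first-class generator produces raw ECG and
   belt waveforms with exact ground truth (beat times, breath times,
   injected condition effects), making every downstream stage testable.

## The synthetic generator

### RR model

The tachogram is generated by direct interval modulation:

RR_k = mean_rr + A_LF sin(2*pi*f_LF*t_k + phi_LF)
              + A_HF sin(2*pi*f_HF*t_k + phi_HF) + e_k,

with beat k+1 occurring RR_k after beat k. `f_LF` defaults to 0.1 Hz (the
baroreflex band) and `f_HF` to the respiratory frequency `resp_rate/60`, so
the HF modulation is respiratory-band by construction. The residual e_k
mixes a slow AR(1) component (rho = 0.97; essentially a very-low-frequency
drift) with broadband white noise in proportion `hr_entropy_mix`; the
broadband fraction is what raises approximate entropy, because ApEn has no
tractable inverse to target directly. An integral-pulse-frequency-modulation
beat generator was deliberately not used: the downstream analyses
characterize band powers and regularity only, and direct interval modulation
makes band-power ground truth analytic (an A-sinusoid contributes A^2/2 of
power to its band).

### Respiration model

Breaths are piecewise-asymmetric raised cosines. The B-peak (exhalation
onset) times are the jittered anchor sequence: successive peak-to-peak gaps
are Gaussian around `60/resp_rate` s with SD `bb_jitter_sd` (truncated to
the physiological range 1.5–20 s), so the SD of true BB intervals equals the
injected jitter by construction. Each inter-peak gap splits into expiration
and the following inspiration in ratio 1 : `ie_ratio`; with zero jitter the
per-breath inspiratory/expiratory ratio is exact, under jitter it is exact
in the mean, which is what the phase-duration-ratio feature estimates.
Amplitude enters linearly (5% per-breath CV), so belt gain differences are
exactly multiplicative; the thoracic and abdominal channels are rendered
from one set of true breath times at relative gains 1 and 0.85.

### ECG rendering

A fixed biphasic QRS-like kernel (Gaussian R lobe with Q/S dips) is placed
at each true beat time; morphological realism (P/T waves, ectopy) is a
non-goal. Optional baseline-wander and mains-tone contaminants exercise the
preprocessing filters. Detection on clean renders recovers truth within one
sample, which is what makes "detected = truth" assertions meaningful.

### Cohort structure and calibration

Subject physiology is a vector of multiplicative log-normal random effects
(on mean RR, modulation depths, respiratory rate, amplitude, phase ratio,
breath jitter) shared across that subject's three conditions — the paired
design of the study — plus 3% independent per-recording jitter. Random
effects are rescaled to unit geometric mean across the cohort, so realized
group means track the condition targets even at n = 26; this is calibrated
sampling in the `mvrnorm(empirical = TRUE)` tradition, chosen because the
cohort's purpose is to *embody* stated group conditions, not to estimate
them.

The default profiles encode the published group pattern: Rest at 69.25 bpm
and SICT at 81.07 bpm mean heart rate; SICT with larger overall RR
variability (larger LF depth) but reduced respiratory-band modulation
(lower HF), a more regular tachogram (low broadband mix), larger breathing
amplitude (375 vs 210 units), raised phase ratio (1.04 vs 0.74) and roughly
doubled breath-period jitter (2.6 s vs 1.3 s SD). The Imag profile is
generatively identical to Rest, so Rest-vs-Imag decoding on the default
cohort estimates the null. Between-subject coefficients of variation were
chosen once to approximate the published group SDs (e.g. heart-rate CV
~0.11, amplitude CV ~0.45).

What the generator does **not** emulate: ectopic beats and detector-hostile
noise, cardiorespiratory phase coupling beyond the shared HF frequency,
tidal-volume calibration, and the empirical joint structure of real HRV
metrics. One known consequence: in the generator, lowering the broadband
noise fraction (to lower ApEn in SICT) also lowers RMSSD, whereas the study
observed an ApEn drop with unchanged RMSSD; passing tests therefore show
pipeline correctness on signals with known structure, not physiological
completeness.

## Numerical and methodological choices

* **Welch spectra.** The irregular tachogram is cubic-spline resampled at
  4 Hz and analysed with Hann-windowed, mean-removed 120 s segments at 50%
  overlap: 0.04 Hz (the LF band edge) is resolved with ~9 averages over the
  660 s segment. The publication specifies Welch but none of these
  settings; all are configurable and logged. Band powers integrate the
  one-sided density over [0.04, 0.15) and [0.15, 0.4) Hz; normalization
  divides by total power in [0.04, 0.4) Hz — VLF is excluded because the
  11-minute segment supports no stable VLF estimate. Zero HF power yields
  `NA` for lnHF and LF/HF, never infinities.
* **Units and the mean-RR correction.** Band powers are reported in ms^2
  from the ms-scaled tachogram. The published HF magnitudes (~0.002-0.008
  "ms^2") are orders of magnitude below any plausible ms^2 HF power and
  their unit convention is not recoverable; this package therefore emits
  both raw ms^2 powers and mean-RR-corrected variants and makes no attempt
  to match the printed magnitudes. The correction multiplies each spectral
  power by the subject's mean RR expressed in seconds (800 ms -> 0.8),
  keeping corrected values on a familiar scale; the LF/HF ratio is invariant
  under a common multiplier and is carried in both variants for registry
  completeness.
* **R-peak detection.** Derivative-square-integrate energy with running
  signal/noise thresholds and a 200 ms refractory period, then refinement
  to the ECG extremum with globally resolved lead polarity. The publication
  names no algorithm; this is the standard Pan-Tompkins family.
* **RR artifact rule.** Flag intervals outside [300, 2000] ms or deviating
  more than 30% from an 11-interval running median; flagged intervals at
  least 1.6x the local median are split into equal sub-intervals (missed
  beats, preserving cumulative time), the rest replaced by spline
  interpolation over clean neighbours. More than 20% flagged marks the
  recording unusable — the automated counterpart of excluding a participant
  for excessive artifacts.
* **BB artifact rule.** Same family with respiratory bounds [1.5, 20] s,
  but the deviation threshold is `max(0.4 * median, 3.5 * MAD)`. The MAD
  guard matters: healthy breathing at the study's own variability level
  (BB SDs of 1.3–2.6 s on ~4 s breaths) exceeds a fixed 40% deviation in
  well over 20% of breaths, so a fixed threshold would reject every
  high-variability recording and bias SDBB downward in the rest. With the
  guard, the rule still catches sensor dropouts and doubled detections
  (intervals under 60% of the local median are merged) while leaving
  genuine variability alone.
* **Phase boundaries.** Inspiration is trough-to-peak, expiration is
  peak-to-next-trough, and the "B peak corresponding to exhalation onsets"
  is implemented as the inhalation maximum; the source wording is ambiguous
  and this reading makes the three definitions mutually consistent.
* **ApEn.** m = 2, r = 0.2 x SD of the analysed series, self-matches
  included — the field's convention; the publication states none.
* **Discriminant and ties.** With equal priors (the paired design is
  balanced), the one-dimensional LDA rule is nearest class mean; exact
  boundary hits, and all predictions when the class means coincide, go
  deterministically to the lexicographically lower condition label.
* **Permutation scheme.** The default null swaps the two condition labels
  within each subject independently with probability 1/2 — the
  exchangeability that the paired design actually licenses; a global
  label shuffle is available by configuration. The same 1000 resamples are
  shared across all features of a condition pair, so the maximum statistic
  is taken over a coherent joint null; the threshold is the empirical 95th
  percentile ("higher" convention) of the per-permutation maxima, and
  significance is strict exceedance.
* **Spearman p-values** come from `stats::cor.test` (exact where R provides
  it, asymptotic otherwise). The tonic-phasic correlation is reported with
  an explicit caveat: because phasic = task - tonic, independence of task
  and tonic values already induces a negative correlation (regression to
  the mean), so large negative coefficients partly reflect the construction.
* **Segment timing.** Analysis uses 660 s (11 min) starting at the
  manifest's `induction_end_s` (default 60 s into the 720 s recording),
  mirroring the removal of the trance-induction period. Because beats are
  discrete, the last beat may fall up to one interval before the nominal
  record end; segment selection tolerates a 2 s shortfall.
* **Feature registry.** The exact composition of the published "16 cardiac
  metrics" and "11 respiratory metrics" is not enumerated anywhere; this
  package fixes the registry as the 12 cardiac metrics {heart rate, mean
  RR, SDNN, RMSSD, pNN50, ApEn, LF, HF, LFn, HFn, lnHF, LF/HF} plus the 4
  corrected spectral variants, and {rate, amplitude, phase ratio, SDBB,
  RMSSD-BB} per belt plus the belt-averaged rate. The cohort default is
  n = 26 analysed subjects (the publication variously implies 25-27;
  `n_subjects` is a parameter precisely because no single count is
  authoritative).

## What the acceptance checks do and do not establish

The package's acceptance suite verifies: metric agreement with brute-force
oracles to 1e-9; spectral band recovery of single-frequency modulations;
removal of a built-in HF-heart-rate dependence by the mean-RR correction;
chance-level mean decoding accuracy and familywise error control under a
global null (200 replicates); exact event recovery on clean recordings; and
the phasic-difference arithmetic.

The end-to-end decoding check on the default cohort reproduces the
qualitative pattern — HFn, lnHF, ApEn, SDBB and RMSSD-BB decode Rest vs
SICT significantly in every replicate while Rest vs Imag stays at chance —
but heart rate, respiratory amplitude and phase ratio are *not* robustly
above the familywise threshold across replicates. This is a property of the
study conditions, not a pipeline defect: the published decoding accuracies
for those features (68–71.9%) lie essentially at the maximum-statistic
threshold a 26-subject, 27-feature analysis produces (~71%), so their
significance cannot replicate at a 95% rate at the published effect sizes.
The corresponding acceptance assertion is deliberately left failing rather
than weakening the generator's calibration or the inference.

## Problem sizes

Defaults used throughout the tests and the acceptance script: 26 subjects x
3 conditions x 720 s recordings at 250 Hz; 660 s analysis segments; 1000
permutations per condition pair; 200 replicates for null-calibration
studies; 4 full-pipeline replicates for the end-to-end pattern check. Unit
tests run reduced variants (4-8 subjects, 240-320 s, 200 permutations)
chosen to exercise identical code paths at interactive speed.
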