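# Shared fixtures, generated once per test run. Short durations keep the
# unit tests fast; the end-to-end checks build their own longer recordings.

fix_profile <- function(...) {
  args <- utils::modifyList(
    list(name = "Fix", mean_rr = 900, lf_depth = 0, hf_depth = 0,
         rr_noise_sd = 0, resp_rate = 15, resp_amp = 300, ie_ratio = 0.8,
         bb_jitter_sd = 0, hr_entropy_mix = 0.5),
    list(...)
  )
  do.call(condition_profile, args)
}

# A clean 11-minute RR series with both modulations, reused across tests.
fix_rr_modulated <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      p <- fix_profile(lf_depth = 40, hf_depth = 25, rr_noise_sd = 15,
                       resp_rate = 15)
      val <<- rr_series(generate_rr_series(p, 660, seed = 404)$times)
    }
    val
  }
})

# Small feature table with a known structure for decode/phasic tests.
fix_feature_table <- function(n = 10, effect = 0, seed = 1) {
  withr::with_seed(seed, {
    base <- rnorm(n)
    data.frame(
      subject_id = rep(sprintf("S%02d", seq_len(n)), 3),
      condition = rep(c("Rest", "Imag", "SICT"), each = n),
      f = c(base + rnorm(n, 0, 0.5),
            base + rnorm(n, 0, 0.5),
            base + rnorm(n, 0, 0.5) + effect),
      stringsAsFactors = FALSE
    )
  })
}
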