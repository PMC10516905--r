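# Independent brute-force oracles: plain-loop implementations of every
# definitional metric, kept deliberately separate from the package's code
# paths so agreement is a real check.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

oracle_pnn50 <- function(x) {
  cnt <- 0
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > 50) cnt <- cnt + 1
  100 * cnt / (length(x) - 1)
}

oracle_heart_rate <- function(x) {
  s <- 0
  for (v in x) s <- s + 60000 / v
  s / length(x)
}

# Direct O(n^2) ApEn by explicit template counting (self-matches included).
oracle_apen <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    logs <- numeric(nm)
    for (i in seq_len(nm)) {
      cnt <- 0
      for (j in seq_len(nm)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          d <- abs(x[i + k] - x[j + k])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nm)
    }
    oracle_mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Spearman rho through explicit midranks (ties handled by averaging).
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- 0
      eq <- 0
      for (j in seq_along(v)) {
        if (v[j] < v[i]) less <- less + 1
        if (v[j] == v[i]) eq <- eq + 1
      }
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- midrank(x)
  ry <- midrank(y)
  mx <- oracle_mean(rx)
  my <- oracle_mean(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Single-bin DFT amplitude of a real signal at frequency f (Goertzel-style
# direct sum), used as the spectral oracle for filter attenuation checks.
oracle_tone_amplitude <- function(x, fs, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * abs(sum(x * exp(-2i * pi * f * t))) / n
}

# Fold-by-fold LOSO decoding via the package's own single-fit API is NOT
# used here; this oracle reimplements the whole scheme with explicit loops
# and a closed-form Gaussian discriminant rule.
oracle_loso_da <- function(a, b, labels = c("A", "B")) {
  n <- length(a)
  correct <- 0
  for (s in seq_len(n)) {
    tr_a <- a[-s]
    tr_b <- b[-s]
    m1 <- oracle_mean(tr_a)
    m2 <- oracle_mean(tr_b)
    thr <- (m1 + m2) / 2
    pred <- function(v) {
      if (m1 == m2 || v == thr) return(sort(labels)[1])
      if (m1 > m2) {
        if (v > thr) labels[1] else labels[2]
      } else {
        if (v < thr) labels[1] else labels[2]
      }
    }
    if (pred(a[s]) == labels[1]) correct <- correct + 1
    if (pred(b[s]) == labels[2]) correct <- correct + 1
  }
  100 * correct / (2 * n)
}
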