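#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library functions never disturb a caller's random
#' stream. All stochastic operations in this package route through this
#' helper, which is what makes generator output bit-reproducible.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation. Linear congruential fold of the parent
# seed and one or more stream indices, kept strictly below 2^31 so the result
# is always a valid R integer seed.
child_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(s)
}

# FNV-1a hash of a character scalar, hex string. Used to fingerprint resolved
# configurations in pipeline outputs (provenance, not cryptography).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - (h %/% 2147483648) * 0), as.integer(b))
    h <- (as.double(h) %% 4294967296) * 16777619 %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_trancehrv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
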