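#' Build a single-feature condition-decoding task
#'
#' Assembles the paired observations for one condition pair and one feature:
#' each subject contributes exactly one value per condition. Subjects missing
#' either condition or with a missing feature value are dropped (recorded in
#' the `excluded` attribute).
#'
#' @param table feature table (long: `subject_id`, `condition`, features).
#' @param pair character vector of two condition labels, e.g.
#'   `c("Rest", "SICT")`.
#' @param feature feature column name.
#' @return an object of class `decoding_task`: `a`, `b` (values for the two
#'   conditions, one per subject), `subject_ids`, `pair`, `feature`.
#' @export
decoding_task <- function(table, pair, feature) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop_trancehrv("`pair` must name two distinct conditions")
  }
  if (!feature %in% names(table)) {
    stop_trancehrv("feature `%s` absent from the table", feature)
  }
  ra <- table[table$condition == pair[1], c("subject_id", feature)]
  rb <- table[table$condition == pair[2], c("subject_id", feature)]
  if (anyDuplicated(ra$subject_id) || anyDuplicated(rb$subject_id)) {
    stop_trancehrv("each subject must contribute exactly one observation per condition")
  }
  ids <- intersect(ra$subject_id, rb$subject_id)
  a <- ra[[feature]][match(ids, ra$subject_id)]
  b <- rb[[feature]][match(ids, rb$subject_id)]
  ok <- is.finite(a) & is.finite(b)
  structure(
    list(a = a[ok], b = b[ok], subject_ids = ids[ok],
         pair = pair, feature = feature),
    class = "decoding_task"
  )
}

#' Fit a two-class linear discriminant on one feature
#'
#' Gaussian linear discriminant with pooled within-class variance and equal
#' priors. In one dimension with equal priors this reduces to a midpoint
#' threshold between the class means: an observation is assigned to the
#' class whose mean is nearer. Observations exactly on the boundary — and
#' all observations when the class means coincide — are assigned to the
#' lexicographically lower class label (deterministic tie-break).
#'
#' @param train_values numeric feature values.
#' @param train_labels class labels (two distinct values required).
#' @return an object of class `lda1d` with `means`, `pooled_sd`,
#'   `threshold`, `labels` and `tie_label`; supports [predict()].
#' @export
fit_linear_discriminant <- function(train_values, train_labels) {
  labs <- sort(unique(as.character(train_labels)))
  if (length(labs) != 2L) {
    stop_trancehrv("training set must contain exactly two classes (got %d)", length(labs))
  }
  x1 <- train_values[train_labels == labs[1]]
  x2 <- train_values[train_labels == labs[2]]
  m <- c(mean(x1), mean(x2))
  ss <- sum((x1 - m[1])^2) + sum((x2 - m[2])^2)
  dfree <- length(x1) + length(x2) - 2L
  structure(
    list(means = stats::setNames(m, labs),
         pooled_sd = if (dfree > 0) sqrt(ss / dfree) else 0,
         threshold = mean(m),
         labels = labs,
         tie_label = labs[1]),
    class = "lda1d"
  )
}

#' @export
predict.lda1d <- function(object, newdata, ...) {
  m <- object$means
  labs <- object$labels
  out <- rep(object$tie_label, length(newdata))
  if (m[1] != m[2]) {
    hi_lab <- labs[which.max(m)]
    lo_lab <- labs[which.min(m)]
    thr <- object$threshold
    out[newdata > thr] <- hi_lab
    out[newdata < thr] <- lo_lab
  }
  out
}

# Vectorized leave-one-subject-out decoding accuracy for a paired
# single-feature task. `S` is an n_perm x n logical matrix of within-subject
# label swaps (a FALSE row reproduces the observed labelling); returns one DA
# (percent) per row. With equal priors the 1-D LDA prediction is
# nearest-class-mean; ties and equal-mean degeneracies go to the
# lexicographically lower label of `pair`.
loso_da_core <- function(a, b, S, pair) {
  n <- length(a)
  np <- nrow(S)
  A <- matrix(a, np, n, byrow = TRUE)
  B <- matrix(b, np, n, byrow = TRUE)
  XA <- ifelse(S, B, A)  # value currently carrying label pair[1]
  XB <- ifelse(S, A, B)
  mA <- (rowSums(XA) - XA) / (n - 1)  # fold-wise training means
  mB <- (rowSums(XB) - XB) / (n - 1)
  thr <- (mA + mB) / 2
  tie_is_a <- pair[1] < pair[2]  # lexicographically lower label wins ties
  up_a <- mA > mB

  corr_a <- (up_a & XA > thr) | (!up_a & mA < mB & XA < thr)
  corr_b <- (up_a & XB < thr) | (!up_a & mA < mB & XB > thr)
  deg <- (mA == mB) | (XA == thr)
  corr_a[deg] <- tie_is_a
  deg_b <- (mA == mB) | (XB == thr)
  corr_b[deg_b] <- !tie_is_a
  100 * (rowSums(corr_a) + rowSums(corr_b)) / (2 * n)
}

#' Leave-one-subject-out decoding accuracy
#'
#' For each subject in turn, a linear discriminant is trained on the paired
#' observations of all remaining subjects and used to classify the held-out
#' subject's two observations; decoding accuracy is the percentage of
#' correctly classified held-out observations pooled over all folds.
#'
#' @param task a `decoding_task` with >= 3 subjects.
#' @return decoding accuracy in percent, with attributes `n_subjects` and
#'   `n_observations` (number of classified test observations).
#' @export
loso_decode <- function(task) {
  stopifnot(inherits(task, "decoding_task"))
  n <- length(task$a)
  if (n < 3L) stop_trancehrv("LOSO decoding requires >= 3 subjects")
  da <- loso_da_core(task$a, task$b, matrix(FALSE, 1L, n), task$pair)
  structure(da, n_subjects = n, n_observations = 2L * n)
}

#' Permutation null distribution of decoding accuracy
#'
#' Re-runs the full leave-one-subject-out decoding under label permutations.
#' The default scheme swaps the two condition labels within each subject
#' independently with probability 1/2, preserving the paired structure of
#' the design; `scheme = "global"` instead shuffles all `2n` labels freely.
#' Deterministic under `seed`.
#'
#' @param task a `decoding_task`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param scheme `"within_subject"` (default) or `"global"`.
#' @return numeric vector of `n_perm` permuted decoding accuracies.
#' @export
permutation_null <- function(task, n_perm = 1000, seed = 1L,
                             scheme = c("within_subject", "global")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(task, "decoding_task"))
  if (n_perm < 1L) stop_trancehrv("`n_perm` must be >= 1")
  n <- length(task$a)
  if (scheme == "within_subject") {
    S <- with_seed(seed, matrix(stats::runif(n_perm * n) < 0.5, n_perm, n))
    return(loso_da_core(task$a, task$b, S, task$pair))
  }
  # global shuffle: labels lose their one-per-condition-per-subject structure
  labs <- sort(task$pair)
  vals <- c(task$a, task$b)
  subj <- rep(seq_len(n), 2L)
  true_labs <- rep(task$pair, each = n)
  with_seed(seed, vapply(seq_len(n_perm), function(p) {
    pl <- sample(true_labs)
    correct <- 0L
    for (s in seq_len(n)) {
      tr <- subj != s
      if (length(unique(pl[tr])) < 2L) next
      fit <- fit_linear_discriminant(vals[tr], pl[tr])
      pred <- predict(fit, vals[!tr])
      correct <- correct + sum(pred == pl[!tr])
    }
    100 * correct / (2L * n)
  }, numeric(1)))
}

#' Familywise threshold from the permutation maximum statistic
#'
#' Takes, for each permutation, the maximum decoding accuracy across all
#' features (the same permutation resamples must be shared across features),
#' and returns the empirical `1 - alpha` quantile of these maxima using the
#' "higher" convention (the smallest observed maximum with cumulative
#' frequency >= 1 - alpha). A feature is significant iff its observed
#' accuracy strictly exceeds the threshold.
#'
#' @param nulls matrix of permuted accuracies, `n_perm` rows x features
#'   columns (a single feature may be passed as a vector).
#' @param alpha familywise error level.
#' @param observed optional named vector of observed accuracies per feature;
#'   when given, per-feature significance flags are returned.
#' @return list: `threshold`, `max_null` (the `n_perm` maxima), and
#'   `significant` (when `observed` is supplied).
#' @export
max_statistic_threshold <- function(nulls, alpha = 0.05, observed = NULL) {
  if (is.vector(nulls)) nulls <- matrix(nulls, ncol = 1L)
  if (!is.matrix(nulls) || any(!is.finite(nulls))) {
    stop_trancehrv("`nulls` must be a finite numeric matrix (n_perm x features)")
  }
  if (alpha <= 0 || alpha > 1) stop_trancehrv("`alpha` must lie in (0, 1]")
  maxima <- do.call(pmax, as.data.frame(nulls))
  s <- sort(maxima)
  k <- max(1L, ceiling((1 - alpha) * length(s)))
  thr <- s[k]
  out <- list(threshold = thr, max_null = maxima)
  if (!is.null(observed)) {
    if (length(observed) != ncol(nulls)) {
      stop_trancehrv("`observed` must have one accuracy per null column")
    }
    out$significant = observed > thr
  }
  out
}

#' Decode all features for the configured condition pairs
#'
#' Runs single-feature LOSO decoding for every feature and condition pair,
#' with one shared set of `n_perm` within-subject label-swap permutations
#' per pair (so the maximum statistic is taken over a coherent joint null),
#' and applies the familywise maximum-statistic threshold.
#'
#' @param table feature table (long format).
#' @param features feature columns to decode; default all cardiac +
#'   respiratory registry features present in the table.
#' @param pairs list of condition pairs; default the three pairings of
#'   Rest/Imag/SICT present in the table.
#' @param n_perm permutations per pair.
#' @param alpha familywise error level.
#' @param seed integer seed (one independent child per pair).
#' @param scheme permutation scheme, see [permutation_null()].
#' @return object of class `decoding_report`: data frame `results` (pair,
#'   feature, da, n_subjects, threshold, significant) plus `thresholds` and
#'   `nulls` per pair.
#' @export
decode_feature_table <- function(table, features = NULL, pairs = NULL,
                                 n_perm = 1000, alpha = 0.05, seed = 1L,
                                 scheme = "within_subject") {
  conds <- unique(table$condition)
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(conds), 2L, simplify = FALSE)
  }
  if (is.null(features)) {
    features <- intersect(c(cardiac_feature_names(), resp_feature_names()),
                          names(table))
  }
  rows <- list()
  thresholds <- list()
  nulls_all <- list()
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    pair_key <- paste(pair, collapse = "_vs_")
    tasks <- lapply(features, function(f) decoding_task(table, pair, f))
    names(tasks) <- features
    obs <- vapply(tasks, loso_decode, numeric(1))
    n <- length(tasks[[1]]$a)
    pair_seed <- child_seed(seed, 100L + pi)
    if (scheme == "within_subject") {
      S <- with_seed(pair_seed, matrix(stats::runif(n_perm * n) < 0.5, n_perm, n))
      nulls <- vapply(tasks, function(tk) {
        loso_da_core(tk$a, tk$b, S, pair)
      }, numeric(n_perm))
    } else {
      nulls <- vapply(tasks, function(tk) {
        permutation_null(tk, n_perm = n_perm, seed = pair_seed, scheme = scheme)
      }, numeric(n_perm))
    }
    ms <- max_statistic_threshold(nulls, alpha = alpha, observed = obs)
    rows[[pi]] <- data.frame(
      pair = pair_key, feature = features, da = unname(obs),
      n_subjects = n, threshold = ms$threshold,
      significant = unname(ms$significant), stringsAsFactors = FALSE
    )
    thresholds[[pair_key]] <- ms$threshold
    nulls_all[[pair_key]] <- nulls
  }
  structure(
    list(results = do.call(rbind, rows), thresholds = thresholds,
         nulls = nulls_all, n_perm = n_perm, alpha = alpha, scheme = scheme),
    class = "decoding_report"
  )
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> %d features x %d pairs, %d permutations, alpha=%.2f\n",
              length(unique(x$results$feature)),
              length(x$thresholds), x$n_perm, x$alpha))
  sig <- x$results[x$results$significant, c("pair", "feature", "da", "threshold")]
  if (nrow(sig)) {
    cat("significant features:\n")
    print(sig, row.names = FALSE)
  } else {
    cat("no significant features\n")
  }
  invisible(x)
}
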