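#' Phasic (task minus rest) values of a metric across subjects
#'
#' For every subject with a Rest observation of `metric`, computes the tonic
#' value (Rest) and the phasic reactivity for each task condition as the
#' exact difference task minus Rest. Subjects missing the Rest condition are
#' excluded and reported in the `excluded` attribute.
#'
#' @param table a feature table: data frame with columns `subject_id`,
#'   `condition` and one column per feature.
#' @param metric feature column name.
#' @param tasks task condition labels; default `c("Imag", "SICT")`.
#' @param rest rest condition label.
#' @return data frame with columns `subject_id`, `metric`, `tonic`, and one
#'   `phasic_<task>` column per task (NA when that task is missing);
#'   attribute `excluded` lists subjects without a Rest observation.
#' @export
compute_phasic <- function(table, metric, tasks = c("Imag", "SICT"),
                           rest = "Rest") {
  if (!metric %in% names(table)) {
    stop_trancehrv("metric `%s` absent from the feature table", metric)
  }
  subjects <- unique(table$subject_id)
  rest_rows <- table[table$condition == rest, c("subject_id", metric)]
  excluded <- setdiff(subjects, rest_rows$subject_id)
  keep <- setdiff(subjects, excluded)
  out <- data.frame(
    subject_id = keep,
    metric = metric,
    tonic = rest_rows[[metric]][match(keep, rest_rows$subject_id)],
    stringsAsFactors = FALSE
  )
  for (task in tasks) {
    task_rows <- table[table$condition == task, c("subject_id", metric)]
    tv <- task_rows[[metric]][match(keep, task_rows$subject_id)]
    out[[paste0("phasic_", tolower(task))]] <- tv - out$tonic
  }
  attr(out, "excluded") <- excluded
  out
}

#' Spearman correlation between tonic and phasic values
#'
#' Rank correlation across subjects between the tonic (Rest) value and the
#' phasic (task minus Rest) reactivity of a metric, with a two-sided
#' p-value. Note the built-in coupling: since the phasic value subtracts the
#' tonic value, even a task value independent of rest yields a negative
#' correlation in expectation (regression to the mean); interpret the
#' magnitude against that baseline.
#'
#' @param records output of [compute_phasic()].
#' @param task task label whose `phasic_<task>` column is correlated.
#' @return list: `rho`, `p`, `n`, `task`. `rho`/`p` are `NA` when either
#'   vector is constant.
#' @export
phasic_tonic_correlation <- function(records, task = "SICT") {
  col <- paste0("phasic_", tolower(task))
  if (!col %in% names(records)) stop_trancehrv("no phasic column for task `%s`", task)
  ok <- stats::complete.cases(records$tonic, records[[col]])
  x <- records$tonic[ok]
  y <- records[[col]][ok]
  if (length(x) < 5L) stop_trancehrv("phasic-tonic correlation requires >= 5 subjects")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x), task = task))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), task = task)
}

#' Dependence of an HRV metric on heart rate or respiratory rate
#'
#' Pearson correlation, over all subject-condition observations of a feature
#' table, between a metric and a physiological covariate (heart rate or
#' respiratory rate). Used to verify that mean-RR-corrected spectral metrics
#' no longer depend on heart rate (two-sided p > 0.05).
#'
#' @param table feature table (long: one row per subject-condition).
#' @param metric feature column name.
#' @param covariate covariate column name, e.g. `"heart_rate"` or
#'   `"resp_rate_mean"`.
#' @return list: `r`, `p`, `n`.
#' @export
dependence_check <- function(table, metric, covariate = "heart_rate") {
  for (col in c(metric, covariate)) {
    if (!col %in% names(table)) stop_trancehrv("column `%s` absent from table", col)
  }
  ok <- stats::complete.cases(table[[metric]], table[[covariate]])
  x <- table[[metric]][ok]
  y <- table[[covariate]][ok]
  if (length(x) < 5L) stop_trancehrv("dependence check requires >= 5 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
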