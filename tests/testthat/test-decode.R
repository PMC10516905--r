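test_that("1-D discriminant reduces to the midpoint threshold", {
  fit <- fit_linear_discriminant(c(-1, 0, 1, 9, 10, 11),
                                 rep(c("A", "B"), each = 3))
  expect_equal(fit$threshold, 5)
  expect_identical(predict(fit, c(4.9, 5.1)), c("A", "B"))
  # exactly on the boundary: deterministic tie-break to the lower label
  expect_identical(predict(fit, 5), "A")
  expect_error(fit_linear_discriminant(1:4, rep("A", 4)), "two classes")
})

test_that("identical class means degenerate to the documented tie-break", {
  fit <- fit_linear_discriminant(c(1, 2, 3, 3, 2, 1),
                                 rep(c("Rest", "SICT"), each = 3))
  expect_identical(predict(fit, c(-10, 0, 10)), rep("Rest", 3))
})

test_that("discriminant predictions match MASS::lda on random data", {
  withr::with_seed(19, {
    for (i in 1:25) {
      x <- stats::rnorm(40, sample(c(0, 2), 1), 1)
      g <- rep(c("A", "B"), each = 20)
      x[g == "B"] <- x[g == "B"] + stats::runif(1, -1, 3)
      fit <- fit_linear_discriminant(x, g)
      new <- stats::rnorm(15, 1, 2)
      ref <- MASS::lda(data.frame(v = x), grouping = g,
                       prior = c(0.5, 0.5))
      ref_pred <- as.character(stats::predict(ref,
                                              data.frame(v = new))$class)
      expect_identical(predict(fit, new), ref_pred)
    }
  })
})

test_that("LOSO decoding matches a fold-by-fold oracle", {
  # hand-checkable 4-subject task
  a <- c(1, 2, 3, 4)       # condition A values per subject
  b <- c(10, 9, 2.5, 12)   # subject 3 overlaps the A range
  tab <- data.frame(subject_id = rep(sprintf("s%d", 1:4), 2),
                    condition = rep(c("A", "B"), each = 4),
                    f = c(a, b))
  tk <- decoding_task(tab, c("A", "B"), "f")
  expect_equal(as.numeric(loso_decode(tk)), oracle_loso_da(a, b, c("A", "B")))

  withr::with_seed(27, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      av <- stats::rnorm(n)
      bv <- stats::rnorm(n, sample(0:2, 1))
      tab2 <- data.frame(subject_id = rep(seq_len(n), 2),
                         condition = rep(c("A", "B"), each = n),
                         f = c(av, bv))
      tk2 <- decoding_task(tab2, c("A", "B"), "f")
      expect_equal(as.numeric(loso_decode(tk2)),
                   oracle_loso_da(av, bv, c("A", "B")))
    }
  })
})

test_that("perfect separation decodes at 100% and dominates its null", {
  tab <- fix_feature_table(n = 12, effect = 50, seed = 2)
  tk <- decoding_task(tab, c("Rest", "SICT"), "f")
  expect_equal(as.numeric(loso_decode(tk)), 100)
  null <- permutation_null(tk, n_perm = 500, seed = 3)
  expect_true(all(null < 100))
})

test_that("null features decode at chance on average", {
  withr::with_seed(64, {
    das <- replicate(60, {
      tab <- fix_feature_table(n = 26, effect = 0, seed = sample.int(1e6, 1))
      as.numeric(loso_decode(decoding_task(tab, c("Rest", "SICT"), "f")))
    })
    expect_lt(abs(mean(das) - 50), 3)
  })
})

test_that("permutation nulls are deterministic under seed and sized correctly", {
  tab <- fix_feature_table(n = 8, effect = 1, seed = 5)
  tk <- decoding_task(tab, c("Rest", "SICT"), "f")
  n1 <- permutation_null(tk, n_perm = 100, seed = 11)
  n2 <- permutation_null(tk, n_perm = 100, seed = 11)
  expect_identical(n1, n2)
  expect_length(n1, 100)
  expect_false(identical(n1, permutation_null(tk, 100, seed = 12)))
  expect_error(permutation_null(tk, n_perm = 0), "n_perm")
  # global scheme runs and is deterministic too
  g1 <- permutation_null(tk, n_perm = 20, seed = 4, scheme = "global")
  g2 <- permutation_null(tk, n_perm = 20, seed = 4, scheme = "global")
  expect_identical(g1, g2)
})

test_that("the maximum statistic dominates per-feature quantiles", {
  withr::with_seed(41, {
    nulls <- matrix(stats::rnorm(500 * 6, 50, 5), 500, 6)
    ms <- max_statistic_threshold(nulls, alpha = 0.05)
    per_feature <- apply(nulls, 2, stats::quantile, probs = 0.95, type = 1)
    expect_true(all(ms$threshold >= per_feature))
    # alpha = 1 gives the minimum of the max distribution
    expect_equal(max_statistic_threshold(nulls, alpha = 1)$threshold,
                 min(ms$max_null))
    expect_error(max_statistic_threshold(matrix(c(1, NA), 1), 0.05), "finite")
  })
})

test_that("significance is strict exceedance of the familywise threshold", {
  nulls <- matrix(rep(c(50, 60), each = 100), 100, 2)
  obs <- c(60, 61)
  ms <- max_statistic_threshold(nulls, alpha = 0.05, observed = obs)
  expect_equal(ms$threshold, 60)
  expect_identical(unname(ms$significant), c(FALSE, TRUE))
})

test_that("familywise error of the max-statistic test is controlled at alpha", {
  # global null: 27 exchangeable features, 26 subjects; modest replicate and
  # permutation counts keep the check quick while bounding the FWER estimate
  withr::with_seed(77, {
    n_rep <- 60
    fp <- replicate(n_rep, {
      n <- 26
      tab <- data.frame(subject_id = rep(seq_len(n), 2),
                        condition = rep(c("Rest", "SICT"), each = n))
      for (j in 1:27) tab[[paste0("f", j)]] <- stats::rnorm(2 * n)
      rep_seed <- sample.int(2^30, 1)
      rpt <- decode_feature_table(tab, features = paste0("f", 1:27),
                                  pairs = list(c("Rest", "SICT")),
                                  n_perm = 200, seed = rep_seed)
      any(rpt$results$significant)
    })
    fwer <- mean(fp)
    se <- sqrt(0.05 * 0.95 / n_rep)
    expect_lte(fwer, 0.05 + 2 * se)
  })
})

test_that("decoding a paper-scale effect clears the familywise threshold", {
  tab <- fix_feature_table(n = 26, effect = 3, seed = 9)
  withr::with_seed(10, {
    for (j in 1:8) tab[[paste0("null", j)]] <- stats::rnorm(nrow(tab))
  })
  rpt <- decode_feature_table(tab, features = c("f", paste0("null", 1:8)),
                              pairs = list(c("Rest", "SICT")),
                              n_perm = 500, seed = 21)
  res <- rpt$results
  expect_true(res$significant[res$feature == "f"])
  expect_equal(sum(res$significant), 1)
})
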