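test_that("PFS ratios classify clinical benefit at the 1.3 threshold", {
  r <- pfs_ratio(c(58, 17, 40, NA), c(61, 84, 40, 30))
  expect_equal(r$ratio, c(61 / 58, 84 / 17, 1, NA), tolerance = 1e-12)
  expect_identical(r$positive, c(FALSE, TRUE, FALSE, NA))
  expect_error(pfs_ratio(0, 10), "zero")
})

test_that("Clopper-Pearson endpoints match tail-equation root finding", {
  ci <- clopper_pearson(19, 25)
  expect_equal(round(ci[["low"]], 4), 0.5487)
  expect_equal(round(ci[["high"]], 4), 0.9064)
  expect_identical(clopper_pearson(0, 10)[["low"]], 0)
  expect_identical(clopper_pearson(10, 10)[["high"]], 1)
  for (k in c(1, 7, 9)) {
    oracle <- clopper_pearson_oracle(k, 10)
    got <- clopper_pearson(k, 10)
    expect_lt(abs(got[["low"]] - oracle[1]), 1e-6)
    expect_lt(abs(got[["high"]] - oracle[2]), 1e-6)
  }
})

test_that("the exact binomial test equals tail enumeration", {
  expect_lt(exact_binomial(19, 25, 0.30, "greater")$p_value, 1e-4)
  expect_identical(exact_binomial(0, 25, 0.30, "greater")$p_value, 1)
  # full enumeration over all 11 outcomes of n = 10
  enum <- sum(dbinom(3:10, 10, 0.30))
  expect_equal(exact_binomial(3, 10, 0.30, "greater")$p_value, enum,
               tolerance = 1e-12)
  expect_error(exact_binomial(3, 10, 0), "p0")
})

test_that("Barnard's test reproduces the 5/6 vs 1/8 response table", {
  res <- barnard_test(5, 6, 1, 8)
  expect_lt(abs(res$p_value - 0.0104), 0.0005)
  # matrix interface, same table
  expect_equal(barnard_test(matrix(c(5, 1, 1, 7), 2, 2))$p_value, res$p_value)
  # counting the exactly-tied mirror outcome on both sides raises P
  both <- barnard_test(5, 6, 1, 8, ties = "both")
  expect_gt(both$p_value, res$p_value)
})

test_that("Barnard degenerate and symmetry properties hold", {
  expect_identical(barnard_test(6, 6, 8, 8)$p_value, 1)
  set.seed(81)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    p <- barnard_test(x1, n1, x2, n2)$p_value
    expect_gt(p, 0); expect_lte(p, 1)
    # swapping rows and groups simultaneously leaves P unchanged
    p_swap <- barnard_test(n2 - x2, n2, n1 - x1, n1)$p_value
    expect_equal(p_swap, p, tolerance = 1e-9)
  }
})

test_that("Barnard matches the exhaustive enumeration oracle on small tables", {
  set.seed(82)
  cases <- cbind(n1 = sample(2:8, 12, TRUE), n2 = sample(2:8, 12, TRUE))
  for (i in seq_len(nrow(cases))) {
    n1 <- cases[i, "n1"]; n2 <- cases[i, "n2"]
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    got <- barnard_test(x1, n1, x2, n2)$p_value
    oracle <- barnard_oracle(x1, n1, x2, n2)
    expect_lt(abs(got - oracle), 2e-4)
  }
})

test_that("the exact paired Wilcoxon enumerates its null distribution", {
  six <- wilcoxon_signed_rank_exact(c(3, 5, 2, 9, 1, 4))
  expect_identical(six$p_value, 2 / 2^6)   # all-positive differences
  expect_identical(wilcoxon_signed_rank_exact(5)$p_value, 1)

  set.seed(83)
  for (i in 1:8) {
    d <- round(rnorm(8, 0.3, 1), 3)
    d <- d[d != 0]
    got <- wilcoxon_signed_rank_exact(d)
    expect_equal(got$p_value, wilcoxon_oracle(d), tolerance = 1e-12)
    # cross-check against the standard library implementation
    ref <- suppressWarnings(wilcox.test(d, mu = 0, exact = TRUE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # zero differences are dropped with a count
  res <- wilcoxon_signed_rank_exact(c(0, 0, 1, 2, 3))
  expect_identical(res$n_zero, 2L)
  expect_identical(res$n, 3L)
  expect_warning(wilcoxon_signed_rank_exact(c(0, 0)), "zero")
})

test_that("logrank handles identical, separated and hand-computed cases", {
  id <- logrank_test(c(5, 10, 15), c(1, 1, 1), c(5, 10, 15), c(1, 1, 1))
  expect_lt(id$statistic, 1e-9)
  expect_gt(id$p_value, 0.99)

  set.seed(84)
  a <- rexp(6, 1); b <- 10 * rexp(8, 1) + 5
  sep <- logrank_test(a, rep(1, 6), b, rep(1, 8))
  expect_lt(sep$p_value, 0.05)

  # single event per group at distinct times: observed 1 vs expected 0.5,
  # hypergeometric variance 0.25, chi-square = 1
  hand <- logrank_test(1, 1, 2, 1)
  expect_equal(hand$statistic, 1, tolerance = 1e-9)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("Spearman agrees with a rank-then-product-moment oracle", {
  expect_equal(spearman_test(1:10, (1:10)^2)$statistic, 1)
  expect_equal(spearman_test(1:10, -(1:10)^3)$statistic, -1)
  set.seed(85)
  x <- rnorm(13); y <- 0.8 * x + rnorm(13, 0, 0.5)
  got <- spearman_test(x, y)
  expect_equal(got$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_test(rep(1, 10), 1:10), "constant")
  expect_error(spearman_test(1:4, 4:1), "insufficient")
})

test_that("ROC cutoff analysis finds perfect separation and matches oracles", {
  perfect <- roc_cutoff(c(30, 40, 55, 5, 10, 25), c(1, 1, 1, 0, 0, 0))
  expect_identical(perfect$auc, 1)
  expect_identical(perfect$optimal_cutoff, 25)
  for (m in c("accuracy", "ppv", "npv", "recall", "mcc", "f1")) {
    expect_identical(perfect[[m]], 1)
  }

  flat <- roc_cutoff(rep(7, 10), rep(c(TRUE, FALSE), 5))
  expect_identical(flat$auc, 0.5)

  set.seed(86)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    scores <- round(runif(n, 0, 50), 1)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    got <- roc_cutoff(scores, labels)
    expect_equal(got$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    expect_equal(got$auc, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         quiet = TRUE,
                                                         direction = "<"))),
                 tolerance = 1e-9)
    # AUC = 1 exactly when responders and non-responders separate
    expect_identical(got$auc == 1,
                     min(scores[labels]) > max(scores[!labels]))
  }
  expect_error(roc_cutoff(1:5, rep(TRUE, 5)), "both responder classes")
})

test_that("the cohort comparison bundle reproduces the worked outcome table", {
  out <- table2_outcomes()
  cc <- cohort_comparison(out)
  expect_identical(unname(cc$counts$orr), c(5L, 6L, 1L, 8L))
  expect_lt(abs(cc$orr_barnard$p_value - 0.0104), 0.0005)
  # EV010: 61/58 = 1.05, below the 1.3 benefit threshold
  ev010 <- cc$ratios$FPM_guided$ratio[out$patient_id[out$cohort == "FPM_guided"] == "EV010"]
  expect_equal(round(ev010, 2), 1.05)
  expect_false(cc$ratios$FPM_guided$positive[3])
  # guided paired Wilcoxon runs on the complete pairs
  expect_s3_class(cc$paired_wilcoxon$FPM_guided, "fpm_test")
  # imputation policy turns unevaluable previous PFS into evaluable ratios
  cc_floor <- cohort_comparison(out, na_prev_pfs = 6)
  expect_gt(sum(cc_floor$counts$pfs_ratio[c("n1", "n2")]),
            sum(cc$counts$pfs_ratio[c("n1", "n2")]))
})

test_that("Mann-Whitney keeps its nominal size on identical cohorts", {
  set.seed(87)
  rej <- mean(replicate(200, {
    mann_whitney_test(rnorm(10), rnorm(10))$p_value < 0.05
  }))
  expect_lt(rej, 0.12)
})

test_that("an all-improved cohort forces the extreme paired Wilcoxon P", {
  out <- data.frame(
    patient_id = sprintf("p%d", 1:12),
    cohort = rep(c("FPM_guided", "TPC"), each = 6),
    prev_response = "PD", current_response = rep(c("PR", "PD"), each = 6),
    prev_pfs_weeks = rep(10, 12),
    current_pfs_weeks = c(30, 40, 35, 50, 45, 60, 10, 10, 10, 10, 10, 10),
    censored = FALSE,
    treatment_dss = c(30, 35, 32, 45, 40, 50, 0, 2, 1, 0, 3, 1)
  )
  # the TPC arm has all-zero differences, which warns by design
  expect_warning(cc <- cohort_comparison(out), "zero")
  expect_identical(cc$paired_wilcoxon$FPM_guided$p_value, 2 / 2^6)
  expect_identical(cc$paired_wilcoxon$TPC$p_value, 1)
  expect_gt(cc$spearman_dss_pfs$statistic, 0.8)
})
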