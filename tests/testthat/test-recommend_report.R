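test_that("the Cmax gate admits IC50 <= Cmax and nothing else", {
  expect_true(gate_actionable(1, 2))
  expect_true(gate_actionable(2, 2))
  expect_false(gate_actionable(3, 2))
  expect_false(gate_actionable(NA, 2))   # curve never reaches 50%
  expect_false(gate_actionable(1, NA))   # no pharmacokinetic reference
})

mk_results <- function(dss, ic50, cmax, qc = TRUE) {
  data.frame(drug_id = letters[seq_along(dss)], dss = dss, ic50_abs_uM = ic50,
             effectiveness_class = classify_effectiveness(dss),
             cmax_uM = cmax, formulary = TRUE,
             actionable = gate_actionable(ic50, cmax), qc_passed = qc,
             fallback = FALSE, stringsAsFactors = FALSE)
}

test_that("therapies rank by DSS with the IC50/Cmax ratio tie-break", {
  res <- mk_results(dss = c(30, 20), ic50 = c(1, 1), cmax = c(2, 2))
  r <- rank_therapies(res)
  expect_identical(r$recommendations$drug_id, c("a", "b"))
  expect_identical(r$recommendations$rank, 1:2)

  tie <- mk_results(dss = c(25, 25), ic50 = c(0.9, 0.1), cmax = c(1, 1))
  r2 <- rank_therapies(tie)
  expect_identical(r2$recommendations$drug_id, c("b", "a"))

  none <- mk_results(dss = c(30, 20), ic50 = c(5, NA), cmax = c(2, 2))
  r3 <- rank_therapies(none)
  expect_identical(nrow(r3$recommendations), 0L)
  expect_identical(nrow(r3$annex), 2L)
})

test_that("ranking is deterministic across repeated runs", {
  set.seed(91)
  res <- mk_results(dss = runif(8, -5, 40), ic50 = runif(8, 0.1, 5),
                    cmax = runif(8, 0.5, 4))
  expect_identical(rank_therapies(res), rank_therapies(res))
})

test_that("combinations are compared against their best constituent", {
  singles <- mk_results(dss = c(25, 18), ic50 = c(1, 1), cmax = c(2, 2))
  singles$drug_id <- c("topotecan", "cyclophosphamide")
  combos <- mk_results(dss = 40, ic50 = 0.5, cmax = 2)
  combos$drug_id <- combination_id(c("topotecan", "cyclophosphamide"))
  cmp <- compare_combinations(combos, singles)
  expect_identical(cmp$max_constituent_dss, 25)
  expect_true(cmp$exceeds_constituents)

  combos$dss <- 10
  expect_false(compare_combinations(combos, singles)$exceeds_constituents)

  orphan <- combos; orphan$drug_id <- "x+y"
  expect_true(is.na(compare_combinations(orphan, singles)$exceeds_constituents))
})

test_that("additive-effect fixtures flag exactly the super-additive combinations", {
  set.seed(92)
  singles <- mk_results(dss = round(runif(6, 5, 30), 1),
                        ic50 = rep(1, 6), cmax = rep(2, 6))
  pairs <- t(combn(singles$drug_id, 2))
  combo_dss <- vapply(seq_len(nrow(pairs)), function(i) {
    base <- max(singles$dss[singles$drug_id %in% pairs[i, ]])
    base + sample(c(-5, 5), 1)
  }, numeric(1))
  combos <- data.frame(drug_id = apply(pairs, 1, combination_id),
                       dss = combo_dss, ic50_abs_uM = 1,
                       effectiveness_class = classify_effectiveness(combo_dss),
                       cmax_uM = 2, formulary = TRUE, actionable = TRUE,
                       qc_passed = TRUE, fallback = FALSE)
  cmp <- compare_combinations(combos, singles)
  expected <- vapply(seq_len(nrow(cmp)), function(i) {
    agents <- combination_agents(cmp$drug_id[i])[[1]]
    cmp$dss[i] > max(singles$dss[singles$drug_id %in% agents])
  }, logical(1))
  expect_identical(cmp$exceeds_constituents, expected)
})

test_that("tumor-board reports account turnaround against the 28-day window", {
  res <- mk_results(dss = c(30, 5), ic50 = c(1, 2), cmax = c(2, 3))
  rep1 <- tumor_board_report("pt1", res, list(), "2026-01-05", "2026-02-02")
  expect_identical(rep1$turnaround_days, 28L)
  expect_true(rep1$within_window)
  rep2 <- tumor_board_report("pt1", res, list(), "2026-01-05", "2026-02-03")
  expect_false(rep2$within_window)
  expect_error(tumor_board_report("pt1", res, list(), "2026-01-05", "2026-01-01"),
               "precedes")
  expect_identical(rep1$n_effective, 1L)
  expect_identical(rep1$n_moderate, 1L)
})

test_that("QC-failed plates contribute nothing to a report", {
  good <- mk_results(dss = 30, ic50 = 1, cmax = 2)
  bad <- mk_results(dss = 50, ic50 = 0.1, cmax = 2, qc = FALSE)
  bad$drug_id <- "z"
  rep <- tumor_board_report("pt1", rbind(good, bad), list(),
                            "2026-01-05", "2026-01-12")
  expect_false("z" %in% rep$recommendations$drug_id)
  expect_false("z" %in% rep$annex$drug_id)
  # gate soundness over everything recommended
  expect_true(all(rep$recommendations$ic50_abs_uM <= rep$recommendations$cmax_uM))
})

test_that("the feasibility endpoint reproduces the 19-of-25 analysis", {
  fe <- feasibility_endpoint(rep(c(TRUE, FALSE), c(19, 6)), 25)
  expect_equal(fe$proportion, 0.76)
  expect_lt(fe$test$p_value, 1e-4)
  expect_equal(round(fe$test$ci_low, 4), 0.5487)
  expect_equal(round(fe$test$ci_high, 4), 0.9064)
  expect_true(fe$target_met)

  zero <- feasibility_endpoint(rep(FALSE, 10), 10)
  expect_identical(zero$test$p_value, 1)
  full <- feasibility_endpoint(rep(TRUE, 25), 25)
  expect_identical(full$test$ci_high, 1)
})
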