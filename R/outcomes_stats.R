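# Clinical-outcome statistics for FPM cohorts: exact binomial primary
# endpoint with Clopper-Pearson interval, Barnard's unconditional exact test
# for 2x2 response tables, exact paired Wilcoxon, logrank, Mann-Whitney,
# Kruskal-Wallis, Spearman, and ROC-based DSS cutoff analysis.
#
# Standard tests delegate to stats:: / survival::; Barnard's test and the ROC
# cutoff analysis are implemented here (no installed package provides them).

#' Test-result container
#'
#' @param statistic test statistic.
#' @param p_value p-value in (0, 1].
#' @param ci_low,ci_high optional confidence bounds.
#' @param method label.
#' @param n sample size used.
#' @return an `fpm_test` list.
#' @export
fpm_test <- function(statistic = NA_real_, p_value, ci_low = NA_real_,
                     ci_high = NA_real_, method = "", n = NA_integer_) {
  stopifnot(p_value > 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(p_value, 1),
                 ci_low = ci_low, ci_high = ci_high, method = method,
                 n = as.integer(n)),
            class = "fpm_test")
}

#' @export
print.fpm_test <- function(x, ...) {
  cat(sprintf("<fpm_test> %s: statistic %.4g, P = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  if (!is.na(x$ci_low)) cat(sprintf("  95%% CI (%.4f, %.4f)\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' PFS ratio and clinical-benefit classification
#'
#' Ratio of the current regimen's progression-free survival to the same
#' patient's previous regimen; a ratio at or above the threshold (1.3 by
#' convention in precision-oncology trials) counts as a positive outcome.
#' Patients lacking a previous PFS are unevaluable (`NA`), not negative.
#'
#' @param prev_pfs,current_pfs PFS in weeks.
#' @param threshold positive-outcome threshold.
#' @return data.frame with columns `ratio` and `positive` (logical, `NA` when
#'   unevaluable).
#' @export
pfs_ratio <- function(prev_pfs, current_pfs, threshold = 1.3) {
  if (any(!is.na(prev_pfs) & prev_pfs == 0)) stop("previous PFS of zero is invalid")
  ratio <- ifelse(is.na(prev_pfs) | is.na(current_pfs), NA_real_,
                  current_pfs / prev_pfs)
  data.frame(ratio = ratio, positive = ratio >= threshold)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Tail-inversion interval via the beta-quantile relation (the interval
#' reported by `stats::binom.test`).
#'
#' @param k successes, `n` trials, `level` confidence level.
#' @param n,level see above.
#' @return numeric `c(low, high)`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  alpha <- 1 - level
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Exact binomial test
#'
#' One-sided p-values are binomial tail sums; the two-sided p-value sums all
#' outcomes with probability at most that of the observed count (the
#' `stats::binom.test` convention).
#'
#' @param k successes, `n` trials.
#' @param n trials.
#' @param p0 null success probability.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return an `fpm_test` with the Clopper-Pearson 95% interval attached.
#' @export
exact_binomial <- function(k, n, p0 = 0.5,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 1, k >= 0, k <= n)
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie strictly between 0 and 1")
  bt <- stats::binom.test(k, n, p = p0, alternative = alternative)
  ci <- clopper_pearson(k, n, 0.95)
  fpm_test(statistic = k / n, p_value = bt$p.value,
           ci_low = ci[["low"]], ci_high = ci[["high"]],
           method = sprintf("exact binomial vs p0 = %g (%s)", p0, alternative),
           n = n)
}

# pooled-variance score statistic for a 2x2 table, vectorized over outcomes
barnard_score <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  z <- ifelse(v <= 0, 0, (p1 - p2) / sqrt(pmax(v, 1e-300)))
  z[p1 == p2] <- 0
  z
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Groups are the columns: `x1` successes out of `n1` in group 1, `x2` out of
#' `n2` in group 2. The test statistic is the pooled-variance score Z; the
#' p-value is the supremum over the nuisance success probability of the null
#' probability of the extreme region, located on a fine grid (step
#' `grid_step`) and polished by golden-section refinement around the grid
#' maximum.
#'
#' Two-sided extremeness uses `|Z| >= |Z_obs|` with ties in `|Z|` counted on
#' the observed statistic's side only (`ties = "observed"`), the convention of
#' prevailing Barnard implementations; `ties = "both"` also counts
#' exactly-tied mirror outcomes on the opposite side.
#'
#' @param x1,n1,x2,n2 2x2 counts (successes and group sizes); alternatively
#'   `x1` may be a 2x2 matrix with groups as columns and successes in row 1.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @param ties two-sided tie rule, see Details.
#' @param grid_step nuisance-parameter grid resolution.
#' @return an `fpm_test`.
#' @export
barnard_test <- function(x1, n1 = NULL, x2 = NULL, n2 = NULL,
                         alternative = c("two.sided", "greater", "less"),
                         ties = c("observed", "both"), grid_step = 1e-4) {
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  if (is.matrix(x1)) {
    stopifnot(all(dim(x1) == 2L))
    tab <- x1
    x1 <- tab[1, 1]; n1 <- sum(tab[, 1])
    x2 <- tab[1, 2]; n2 <- sum(tab[, 2])
  }
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)

  grid_x1 <- rep(0:n1, times = n2 + 1L)
  grid_x2 <- rep(0:n2, each = n1 + 1L)
  z <- barnard_score(grid_x1, n1, grid_x2, n2)
  z_obs <- barnard_score(x1, n1, x2, n2)
  eps <- 1e-9

  extreme <- switch(
    alternative,
    greater = z >= z_obs - eps,
    less = z <= z_obs + eps,
    two.sided = {
      strictly <- abs(z) > abs(z_obs) + eps
      tied <- abs(abs(z) - abs(z_obs)) <= eps
      same_side <- if (z_obs >= 0) z >= 0 else z <= 0
      if (ties == "observed") strictly | (tied & same_side) else strictly | tied
    }
  )
  if (!any(extreme)) extreme[grid_x1 == x1 & grid_x2 == x2] <- TRUE

  # null probability of the extreme region as a polynomial in the nuisance
  # probability: group the binomial coefficients by total successes
  lc <- lchoose(n1, grid_x1[extreme]) + lchoose(n2, grid_x2[extreme])
  s <- grid_x1[extreme] + grid_x2[extreme]
  N <- n1 + n2
  cs <- rowsum(exp(lc), s)               # coefficient per unique total
  su <- as.numeric(rownames(cs))
  pfun <- function(pi) {
    sum(cs * exp(su * log(pi) + (N - su) * log1p(-pi)))
  }
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  vals <- colSums(cs[, 1L] * exp(outer(su, log(grid)) +
                                   outer(N - su, log1p(-grid))))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  ref <- stats::optimize(pfun, interval = c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  p <- max(vals[i], ref$objective)
  fpm_test(statistic = z_obs, p_value = min(max(p, .Machine$double.xmin), 1),
           method = sprintf("Barnard unconditional test (%s)", alternative),
           n = n1 + n2)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact p-value by enumeration of all 2^n sign assignments of the
#' non-zero differences (n <= 20); the normal approximation with continuity
#' correction is used beyond that. Zero differences are dropped and their
#' count reported.
#'
#' @param x first measurement (or the differences when `y` is `NULL`).
#' @param y optional paired second measurement; differences are `x - y`.
#' @return an `fpm_test` with an extra field `n_zero` (dropped zero
#'   differences).
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no paired differences")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; P = 1")
    res <- fpm_test(statistic = 0, p_value = 1,
                    method = "exact paired Wilcoxon", n = 0L)
    res$n_zero <- n_zero
    return(res)
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 20L) {
    # enumerate the exact null distribution of V over all 2^n sign choices
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(v_all - mu) >= abs(V - mu) - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    # normal approximation with tie correction
    ties <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    p <- 2 * stats::pnorm((abs(V - mu) - 0.5) / sig, lower.tail = FALSE)
    p <- min(1, p)
  }
  res <- fpm_test(statistic = V, p_value = p,
                  method = "exact paired Wilcoxon (two-sided)", n = n)
  res$n_zero <- n_zero
  res
}

#' Two-sample logrank (Mantel-Cox) test
#'
#' Delegates to `survival::survdiff`; right-censored observations carry
#' `event = 0`.
#'
#' @param time1,event1 follow-up times and event indicators for group 1.
#' @param time2,event2 likewise for group 2.
#' @return an `fpm_test` (chi-square statistic on 1 df, two-sided).
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  stopifnot(length(time1) == length(event1), length(time2) == length(event2))
  if (sum(event1) + sum(event2) == 0) stop("no events in either group")
  df <- data.frame(
    time = c(time1, time2),
    event = c(event1, event2),
    group = rep(c("A", "B"), c(length(time1), length(time2)))
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fpm_test(statistic = sd$chisq, p_value = p,
           method = "two-sample logrank (Mantel-Cox)", n = nrow(df))
}

#' Spearman rank correlation test
#'
#' Average ranks for ties; exact p-value (via `stats::cor.test`) for small
#' tie-free samples, t-approximation otherwise.
#'
#' @param x,y paired observations (n >= 5).
#' @return an `fpm_test` whose statistic is rho.
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L) stop("insufficient data: need n >= 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: rho undefined")
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 10 && !has_ties)
  )
  fpm_test(statistic = unname(ct$estimate), p_value = max(ct$p.value, .Machine$double.xmin),
           method = "Spearman rank correlation", n = n)
}

#' Mann-Whitney U test (two independent samples)
#' @param x,y the two samples.
#' @return an `fpm_test`.
#' @export
mann_whitney_test <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  fpm_test(statistic = unname(wt$statistic), p_value = wt$p.value,
           method = "Mann-Whitney U", n = length(x) + length(y))
}

#' Kruskal-Wallis test across k groups
#' @param values numeric vector.
#' @param groups group labels.
#' @return an `fpm_test`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  kt <- stats::kruskal.test(values, factor(groups))
  fpm_test(statistic = unname(kt$statistic), p_value = kt$p.value,
           method = "Kruskal-Wallis", n = length(values))
}

#' ROC analysis of DSS against objective response with optimal cutoff
#'
#' AUC by pairwise concordance (ties count 1/2). The optimal cutoff is chosen
#' by the Youden index over the observed scores with the decision rule
#' "predict responder when score > cutoff"; ties in the index resolve to the
#' smallest cutoff. Confusion metrics are evaluated at that cutoff.
#'
#' @param scores treatment DSS per patient.
#' @param labels logical (or 0/1) responder indicators.
#' @return an `fpm_cutoff` list: `auc`, `optimal_cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `ppv`, `npv`, `recall`, `mcc`, `f1`, `n`.
#' @export
roc_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) stop("both responder classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, `-`)
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)

  cuts <- sort(unique(scores))
  youden <- vapply(cuts, function(c) {
    mean(pos > c) + mean(neg <= c) - 1
  }, numeric(1))
  best <- cuts[which.max(youden)]        # which.max takes the first (smallest) tie

  tp <- sum(pos > best); fn <- sum(pos <= best)
  tn <- sum(neg <= best); fp <- sum(neg > best)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(
    list(auc = auc, optimal_cutoff = best, sensitivity = sens,
         specificity = spec, accuracy = (tp + tn) / length(scores),
         ppv = ppv, npv = npv, recall = sens, mcc = mcc, f1 = f1,
         n = length(scores)),
    class = "fpm_cutoff"
  )
}

#' @export
print.fpm_cutoff <- function(x, ...) {
  cat(sprintf(
    "<fpm_cutoff> AUC %.3f, optimal cutoff > %.4g; accuracy %.3f, PPV %.3f, NPV %.3f, recall %.3f, MCC %.3f, F1 %.3f (n = %d)\n",
    x$auc, x$optimal_cutoff, x$accuracy, x$ppv, x$npv, x$recall, x$mcc, x$f1, x$n))
  invisible(x)
}

objective_response <- function(response) {
  ifelse(is.na(response) | response == "NA", NA, response %in% c("CR", "PR"))
}

#' Read a patient-outcomes table
#'
#' Columns: `patient_id,cohort,prev_response,current_response,prev_pfs_weeks,`
#' `current_pfs_weeks,censored,treatment_dss`. Cohort labels are `FPM_guided`
#' or `TPC`; responses use RECIST-style codes CR/PR/SD/PD (or NA).
#'
#' @param file CSV path.
#' @return data.frame.
#' @export
read_outcomes <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("patient_id", "cohort", "prev_response", "current_response",
            "prev_pfs_weeks", "current_pfs_weeks", "censored")
  missing <- setdiff(need, names(out))
  if (length(missing)) stop("outcomes table lacks columns: ", paste(missing, collapse = ", "))
  if (!"treatment_dss" %in% names(out)) out$treatment_dss <- NA_real_
  out$censored <- as.logical(out$censored)
  bad <- setdiff(stats::na.omit(unique(c(out$prev_response, out$current_response))),
                 c("CR", "PR", "SD", "PD"))
  if (length(bad)) stop("unknown response codes: ", paste(bad, collapse = ", "))
  out
}

#' Full between/within-cohort outcome comparison
#'
#' Runs the FPM outcome analysis bundle on a patient-outcomes table:
#' objective-response 2x2 Barnard test, PFS-ratio >= threshold 2x2 Barnard
#' test, per-cohort exact paired Wilcoxon on previous vs current PFS,
#' Mann-Whitney on PFS ratios between cohorts, logrank on current PFS, and
#' Spearman correlation of treatment DSS with current PFS.
#'
#' @param outcomes data.frame as from [read_outcomes()].
#' @param threshold PFS-ratio clinical-benefit threshold.
#' @param na_prev_pfs policy for absent previous PFS: `"exclude"` leaves such
#'   patients unevaluable for the ratio; a number imputes that floor (weeks).
#' @param config pipeline configuration (supplies defaults).
#' @return list of results; each test is an `fpm_test` (or `NULL` when not
#'   computable) and `counts` reports the 2x2 tables and unevaluable numbers.
#' @export
cohort_comparison <- function(outcomes, threshold = NULL, na_prev_pfs = NULL,
                              config = fpm_config()) {
  threshold <- threshold %||% config$pfs_ratio_threshold
  na_prev_pfs <- na_prev_pfs %||% config$na_prev_pfs
  cohorts <- c("FPM_guided", "TPC")
  if (!all(cohorts %in% outcomes$cohort)) stop("both cohorts must be present")
  g <- outcomes[outcomes$cohort == "FPM_guided", , drop = FALSE]
  t <- outcomes[outcomes$cohort == "TPC", , drop = FALSE]

  # objective response 2x2
  orr <- lapply(list(g, t), function(d) {
    resp <- objective_response(d$current_response)
    c(k = sum(resp, na.rm = TRUE), n = sum(!is.na(resp)))
  })
  orr_test <- barnard_test(orr[[1]]["k"], orr[[1]]["n"], orr[[2]]["k"], orr[[2]]["n"])

  # PFS ratios under the NA-previous-PFS policy
  prep_ratio <- function(d) {
    prev <- d$prev_pfs_weeks
    if (is.numeric(na_prev_pfs)) prev[is.na(prev)] <- na_prev_pfs
    pfs_ratio(prev, d$current_pfs_weeks, threshold)
  }
  rg <- prep_ratio(g); rt <- prep_ratio(t)
  ratio_counts <- c(
    k1 = sum(rg$positive, na.rm = TRUE), n1 = sum(!is.na(rg$positive)),
    k2 = sum(rt$positive, na.rm = TRUE), n2 = sum(!is.na(rt$positive))
  )
  ratio_test <- if (ratio_counts["n1"] >= 1 && ratio_counts["n2"] >= 1) {
    barnard_test(ratio_counts[["k1"]], ratio_counts[["n1"]],
                 ratio_counts[["k2"]], ratio_counts[["n2"]])
  }

  paired_wilcoxon <- lapply(list(FPM_guided = g, TPC = t), function(d) {
    prev <- d$prev_pfs_weeks
    if (is.numeric(na_prev_pfs)) prev[is.na(prev)] <- na_prev_pfs
    keep <- !is.na(prev) & !is.na(d$current_pfs_weeks)
    if (sum(keep) == 0L) return(NULL)
    wilcoxon_signed_rank_exact(d$current_pfs_weeks[keep], prev[keep])
  })

  mw <- if (sum(!is.na(rg$ratio)) >= 1 && sum(!is.na(rt$ratio)) >= 1) {
    mann_whitney_test(rg$ratio[!is.na(rg$ratio)], rt$ratio[!is.na(rt$ratio)])
  }

  lr <- {
    keep_g <- !is.na(g$current_pfs_weeks)
    keep_t <- !is.na(t$current_pfs_weeks)
    ev_g <- as.numeric(!g$censored[keep_g])
    ev_t <- as.numeric(!t$censored[keep_t])
    if (sum(ev_g) + sum(ev_t) >= 1 && sum(keep_g) >= 1 && sum(keep_t) >= 1) {
      logrank_test(g$current_pfs_weeks[keep_g], ev_g,
                   t$current_pfs_weeks[keep_t], ev_t)
    }
  }

  sp <- {
    keep <- !is.na(outcomes$treatment_dss) & !is.na(outcomes$current_pfs_weeks)
    if (sum(keep) >= 5L) {
      spearman_test(outcomes$treatment_dss[keep], outcomes$current_pfs_weeks[keep])
    }
  }

  list(
    counts = list(
      orr = stats::setNames(c(orr[[1]], orr[[2]]), c("k_guided", "n_guided", "k_tpc", "n_tpc")),
      pfs_ratio = ratio_counts,
      unevaluable_ratio = c(FPM_guided = sum(is.na(rg$positive)),
                            TPC = sum(is.na(rt$positive)))
    ),
    ratios = list(FPM_guided = rg, TPC = rt),
    orr_barnard = orr_test,
    pfs_ratio_barnard = ratio_test,
    paired_wilcoxon = paired_wilcoxon,
    mann_whitney_ratio = mw,
    logrank_current_pfs = lr,
    spearman_dss_pfs = sp
  )
}
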