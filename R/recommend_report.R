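# Actionability gating against Cmax, DSS-ranked therapy recommendations,
# combination-vs-constituent comparison, and tumor-board report assembly
# with turnaround/feasibility accounting.

#' Actionability gate: IC50 at or below Cmax
#'
#' A drug is recommendable only when its absolute IC50 does not exceed the
#' maximum clinically achievable plasma concentration; an absent IC50 (the
#' curve never reaches 50% inhibition) or an absent Cmax fails the gate.
#'
#' @param ic50_abs absolute IC50 in uM (vectorized, `NA` allowed).
#' @param cmax Cmax in uM (`NA` allowed).
#' @return logical vector.
#' @export
gate_actionable <- function(ic50_abs, cmax) {
  !is.na(ic50_abs) & !is.na(cmax) & ic50_abs <= cmax
}

#' Rank actionable therapies by DSS
#'
#' Actionable drugs are sorted by DSS descending, ties broken by the smaller
#' IC50/Cmax ratio, then lexicographic drug id. Non-actionable drugs are
#' returned in a separate annex (same ordering), never recommended.
#'
#' @param results data.frame from [score_drugs()].
#' @return list with `recommendations` (rank, drug_id, dss, ic50_abs_uM,
#'   cmax_uM, formulary, is_combination) and `annex`.
#' @export
rank_therapies <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no drug results to rank")
  results$ratio <- results$ic50_abs_uM / results$cmax_uM
  ord <- order(-results$dss, results$ratio, results$drug_id)
  results <- results[ord, , drop = FALSE]
  results$is_combination <- grepl("+", results$drug_id, fixed = TRUE)
  rec <- results[results$actionable, , drop = FALSE]
  annex <- results[!results$actionable, , drop = FALSE]
  if (nrow(rec)) rec$rank <- seq_len(nrow(rec))
  else rec$rank <- integer(0)
  cols <- c("rank", "drug_id", "dss", "ic50_abs_uM", "cmax_uM", "formulary",
            "is_combination", "effectiveness_class")
  rownames(rec) <- rownames(annex) <- NULL
  list(recommendations = rec[cols], annex = annex[setdiff(cols, "rank")])
}

#' Compare combination treatments with their tested constituents
#'
#' Combinations are ranked by DSS and annotated with the best constituent
#' DSS and whether the combination exceeded it.
#'
#' @param combo_results data.frame from [score_drugs()] for combination ids
#'   (agent names joined with `"+"`).
#' @param constituent_results data.frame for single agents.
#' @return data.frame: `drug_id`, `dss`, `max_constituent_dss`,
#'   `exceeds_constituents` (`NA` when no constituent was tested),
#'   `n_constituents_tested`.
#' @export
compare_combinations <- function(combo_results, constituent_results) {
  if (is.null(combo_results) || nrow(combo_results) == 0L) stop("no combinations supplied")
  rows <- lapply(seq_len(nrow(combo_results)), function(i) {
    id <- combo_results$drug_id[i]
    agents <- combination_agents(id)[[1L]]
    hit <- constituent_results[constituent_results$drug_id %in% agents, , drop = FALSE]
    best <- if (nrow(hit)) max(hit$dss) else NA_real_
    data.frame(drug_id = id, dss = combo_results$dss[i],
               max_constituent_dss = best,
               exceeds_constituents = if (nrow(hit)) combo_results$dss[i] > best else NA,
               n_constituents_tested = nrow(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$dss, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a tumor-board report for one patient
#'
#' Recommendations are drawn only from QC-passing plates. Turnaround is
#' counted in whole days from sample receipt (day 0) to the report date; the
#' clinically actionable window is 28 days.
#'
#' @param patient_id patient identifier.
#' @param results data.frame from [score_drugs()] (all of the patient's
#'   drugs; rows with `qc_passed = FALSE` are excluded from ranking).
#' @param qc_results list of the patient's `fpm_qc` objects.
#' @param received_date,report_date ISO-8601 dates.
#' @param cancer_class `"solid"` or `"hematological"`.
#' @param config pipeline thresholds.
#' @return an `fpm_report`.
#' @export
tumor_board_report <- function(patient_id, results, qc_results = list(),
                               received_date, report_date,
                               cancer_class = "solid", config = fpm_config()) {
  received_date <- as.Date(received_date)
  report_date <- as.Date(report_date)
  usable <- results[results$qc_passed, , drop = FALSE]
  ranking <- if (nrow(usable)) rank_therapies(usable) else
    list(recommendations = NULL, annex = NULL)
  cls <- factor(usable$effectiveness_class,
                levels = c("effective", "moderately_effective", "ineffective"))
  counts <- table(cls)
  turnaround <- as.integer(report_date - received_date)
  if (is.na(turnaround) || turnaround < 0) stop("report date precedes receipt date")
  structure(
    list(
      patient_id = patient_id,
      cancer_class = cancer_class,
      recommendations = ranking$recommendations,
      annex = ranking$annex,
      qc_summary = data.frame(
        plate_id = vapply(qc_results, function(q) q$plate_id %||% NA_character_, character(1)),
        z_prime = vapply(qc_results, function(q) q$z_prime, numeric(1)),
        quality_class = vapply(qc_results, function(q) q$quality_class, character(1)),
        passed = vapply(qc_results, function(q) q$passed, logical(1)),
        stringsAsFactors = FALSE
      ),
      n_effective = as.integer(counts[["effective"]]),
      n_moderate = as.integer(counts[["moderately_effective"]]),
      n_ineffective = as.integer(counts[["ineffective"]]),
      received_date = received_date,
      report_date = report_date,
      turnaround_days = turnaround,
      within_window = turnaround <= config$window_days
    ),
    class = "fpm_report"
  )
}

#' @export
print.fpm_report <- function(x, ...) {
  cat(sprintf("<fpm_report %s> (%s) %d recommendations; %d effective / %d moderate / %d ineffective drugs; turnaround %d days (%s)\n",
              x$patient_id, x$cancer_class,
              if (is.null(x$recommendations)) 0L else nrow(x$recommendations),
              x$n_effective, x$n_moderate, x$n_ineffective,
              x$turnaround_days,
              if (x$within_window) "within window" else "outside window"))
  if (!is.null(x$recommendations) && nrow(x$recommendations)) {
    print(utils::head(x$recommendations, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Primary feasibility endpoint
#'
#' Proportion of enrolled patients whose report was returned within the
#' clinically actionable window, with a one-sided exact binomial test against
#' the null proportion (0.30) and the two-sided 95% Clopper-Pearson interval.
#'
#' @param reports list of `fpm_report` objects (or a logical vector of
#'   within-window indicators).
#' @param n_enrolled total enrolled patients.
#' @param config pipeline thresholds (null proportion).
#' @return list: `k`, `n`, `proportion`, `test` (an `fpm_test`),
#'   `target_met` (proportion at or above the 60% target).
#' @export
feasibility_endpoint <- function(reports, n_enrolled, config = fpm_config()) {
  within <- if (is.logical(reports)) reports
  else vapply(reports, function(r) r$within_window, logical(1))
  k <- sum(within)
  if (n_enrolled < 1 || k > n_enrolled) stop("invalid enrollment count")
  test <- exact_binomial(k, n_enrolled, p0 = config$null_proportion,
                         alternative = "greater")
  list(k = k, n = n_enrolled, proportion = k / n_enrolled, test = test,
       target_met = k / n_enrolled >= config$target_proportion)
}
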