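# Pipeline configuration and end-to-end orchestration
# (ingest -> QC -> fit -> score -> report -> outcomes).

#' Pipeline configuration
#'
#' All thresholds default to the study conventions: Z-prime quality bounds
#' 0.5 / -0.5 with the 5,000-RLU luminescence rescue for marginal plates, a
#' 28-day clinically actionable window, a 30% null and 60% target proportion
#' for the feasibility endpoint, and a 1.3 PFS-ratio benefit threshold.
#'
#' @param t DSS activity threshold (percent inhibition).
#' @param effective_gt,ineffective_le DSS effectiveness cutoffs.
#' @param z_high,z_marginal Z-prime class boundaries.
#' @param rescue_rlu marginal-plate rescue threshold on the median
#'   negative-control luminescence (strictly greater passes).
#' @param window_days clinically actionable reporting window.
#' @param null_proportion,target_proportion feasibility endpoint proportions.
#' @param pfs_ratio_threshold clinical-benefit PFS ratio.
#' @param na_prev_pfs `"exclude"` or a numeric floor (weeks) imputed for
#'   absent previous PFS.
#' @param seed integer seed recorded for any randomized stage.
#' @return an `fpm_config` with a stable `hash` of its settings.
#' @export
fpm_config <- function(t = 10, effective_gt = 10, ineffective_le = 0,
                       z_high = 0.5, z_marginal = -0.5, rescue_rlu = 5000,
                       window_days = 28, null_proportion = 0.30,
                       target_proportion = 0.60, pfs_ratio_threshold = 1.3,
                       na_prev_pfs = "exclude", seed = 1L) {
  stopifnot(t > 0, t < 100, z_marginal < z_high, z_high <= 1,
            rescue_rlu >= 0, window_days >= 1,
            null_proportion > 0, null_proportion < 1,
            target_proportion > 0, target_proportion <= 1,
            pfs_ratio_threshold > 0)
  cfg <- list(t = t, effective_gt = effective_gt, ineffective_le = ineffective_le,
              z_high = z_high, z_marginal = z_marginal, rescue_rlu = rescue_rlu,
              window_days = window_days, null_proportion = null_proportion,
              target_proportion = target_proportion,
              pfs_ratio_threshold = pfs_ratio_threshold,
              na_prev_pfs = na_prev_pfs, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "fpm_config")
}

# order-independent content hash of the configuration (djb2 over the
# serialized key=value text; no external digest dependency)
config_hash <- function(cfg) {
  cfg$hash <- NULL
  keys <- sort(names(cfg))
  txt <- paste(keys, vapply(cfg[keys], function(v) paste(format(v, digits = 15), collapse = ","),
                            character(1)),
               sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' @export
print.fpm_config <- function(x, ...) {
  cat("<fpm_config>", x$hash, "\n")
  for (k in setdiff(names(x), "hash")) cat(sprintf("  %s: %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}

#' Scoring configuration embedded in a pipeline configuration
#' @param config an `fpm_config`.
#' @return an `fpm_scoring_config`.
#' @export
as_scoring_config <- function(config) {
  scoring_config(t = config$t, effective_gt = config$effective_gt,
                 ineffective_le = config$ineffective_le)
}

#' Run the full DST pipeline over a set of plates
#'
#' Executes QC, normalization, curve fitting, DSS scoring and tumor-board
#' report assembly for every patient. QC-failed plates contribute no
#' recommendations; a failing stage marks that patient incomplete without
#' aborting the remaining patients. Re-running on the same inputs yields
#' identical output.
#'
#' @param plates list of `fpm_plate` objects (one or more per patient).
#' @param drug_library data.frame from [read_drug_library()] (optional).
#' @param config an `fpm_config`.
#' @param report_dates optional named vector/list of report dates per patient
#'   (defaults to each patient's latest plate readout date).
#' @return an `fpm_run`: `reports` (per completed patient), `qc` (data.frame
#'   over all plates), `drug_results` (combined data.frame), `incomplete`
#'   (patient ids with the recorded error), `config_hash`.
#' @export
run_pipeline <- function(plates, drug_library = NULL, config = fpm_config(),
                         report_dates = NULL) {
  if (length(plates) == 0L) stop("no plates supplied")
  scfg <- as_scoring_config(config)
  patients <- split(plates, vapply(plates, function(p) p$patient_id, character(1)))

  qc_rows <- list(); reports <- list(); drug_rows <- list(); incomplete <- list()
  for (pid in names(patients)) {
    res <- tryCatch({
      pl <- patients[[pid]]
      qcs <- lapply(pl, qc_plate, config = config)
      qc_rows[[pid]] <- data.frame(
        patient_id = pid,
        plate_id = vapply(qcs, `[[`, "", "plate_id"),
        cancer_class = vapply(pl, `[[`, "", "cancer_class"),
        z_prime = vapply(qcs, `[[`, 0, "z_prime"),
        quality_class = vapply(qcs, `[[`, "", "quality_class"),
        passed = vapply(qcs, `[[`, TRUE, "passed"),
        rescue_applied = vapply(qcs, `[[`, TRUE, "rescue_applied"),
        stringsAsFactors = FALSE
      )
      scored <- list()
      for (i in seq_along(pl)) {
        if (!qcs[[i]]$passed) next
        curves <- fit_plate(pl[[i]], config)
        pts <- normalize_plate(pl[[i]], qcs[[i]]$stats)
        fb <- split(pts[c("x", "inhibition")], pts$drug_id)
        scored[[length(scored) + 1L]] <-
          score_drugs(curves, drug_library, scfg, qc_passed = TRUE,
                      fallback_points = fb)
      }
      if (length(scored) == 0L) stop("no QC-passing plates for patient ", pid)
      results <- do.call(rbind, scored)
      received <- min(do.call(c, lapply(pl, `[[`, "received_date")), na.rm = TRUE)
      rep_date <- report_dates[[pid]] %||%
        max(do.call(c, lapply(pl, `[[`, "readout_date")), na.rm = TRUE)
      list(report = tumor_board_report(pid, results, qcs, received, rep_date,
                                       cancer_class = pl[[1L]]$cancer_class,
                                       config = config),
           results = results)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      incomplete[[pid]] <- conditionMessage(res)
    } else {
      reports[[pid]] <- res$report
      drug_rows[[pid]] <- cbind(patient_id = pid, res$results)
    }
  }
  structure(
    list(reports = reports,
         qc = do.call(rbind, c(qc_rows, list(make.row.names = FALSE))),
         drug_results = if (length(drug_rows)) do.call(rbind, c(drug_rows, list(make.row.names = FALSE))),
         incomplete = incomplete,
         config_hash = config$hash),
    class = "fpm_run"
  )
}

#' @export
print.fpm_run <- function(x, ...) {
  cat(sprintf("<fpm_run %s> %d patients reported, %d incomplete, %d plates (%d passed QC)\n",
              x$config_hash, length(x$reports), length(x$incomplete),
              nrow(x$qc), sum(x$qc$passed)))
  invisible(x)
}
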