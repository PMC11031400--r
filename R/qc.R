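# Plate quality control: Z-prime score from on-plate controls and the
# three-class pass/fail decision used for every DST assay plate.

#' Summary statistics of a plate's control wells
#'
#' @param plate an `fpm_plate` with luminescence readout.
#' @return an `fpm_control_stats` list: `mu_p`, `sigma_p` (positive-control
#'   mean / sample s.d.), `mu_n`, `sigma_n` (negative controls), `median_neg`
#'   (median negative-control RLU, the plate's signal ceiling), `n_pos`,
#'   `n_neg`.
#' @export
control_stats <- function(plate) {
  stopifnot(inherits(plate, "fpm_plate"))
  pos <- plate$wells$rlu[plate$wells$content == "positive_control"]
  neg <- plate$wells$rlu[plate$wells$content == "negative_control"]
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("insufficient controls: need >= 2 positive and >= 2 negative control wells")
  }
  structure(
    list(
      mu_p = mean(pos), sigma_p = stats::sd(pos),
      mu_n = mean(neg), sigma_n = stats::sd(neg),
      median_neg = stats::median(neg),
      n_pos = length(pos), n_neg = length(neg)
    ),
    class = "fpm_control_stats"
  )
}

#' Z-prime plate quality score
#'
#' `Z' = 1 - 3 * (sigma_p + sigma_n) / |mu_p - mu_n|`, computed from the
#' sample means and standard deviations (n - 1 denominator) of the positive
#' and negative control wells. Symmetric under swapping the control labels
#' and invariant under a positive affine rescaling of all RLU values.
#'
#' @param stats an `fpm_control_stats`, or the positive-control mean `mu_p`.
#' @param sigma_p,mu_n,sigma_n control statistics when `stats` is numeric.
#' @return the Z-prime score (a real number, at most 1).
#' @export
z_prime <- function(stats, sigma_p = NULL, mu_n = NULL, sigma_n = NULL) {
  if (inherits(stats, "fpm_control_stats")) {
    mu_p <- stats$mu_p; sigma_p <- stats$sigma_p
    mu_n <- stats$mu_n; sigma_n <- stats$sigma_n
  } else {
    mu_p <- stats
  }
  if (!all(is.finite(c(mu_p, sigma_p, mu_n, sigma_n)))) {
    stop("control statistics must be finite")
  }
  if (mu_p == mu_n) {
    stop("undefined separation: positive and negative control means are equal")
  }
  1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)
}

#' Classify a plate from its Z-prime score and negative-control median
#'
#' High quality when `0.5 <= z <= 1`, marginal when `-0.5 <= z < 0.5`, failed
#' when `z < -0.5`. High-quality plates pass; marginal plates are rescued
#' (pass) only when the median negative-control luminescence exceeds 5,000
#' RLU, guarding against globally dead plates.
#'
#' @param z Z-prime score (at most 1).
#' @param median_neg median RLU of the plate's negative-control wells.
#' @param config pipeline thresholds from [fpm_config()].
#' @return an `fpm_qc` list: `z_prime`, `quality_class` (high / marginal /
#'   failed), `passed`, `rescue_applied`.
#' @export
classify_plate <- function(z, median_neg, config = fpm_config()) {
  stopifnot(is.finite(z), z <= 1, is.finite(median_neg), median_neg >= 0)
  quality_class <-
    if (z >= config$z_high) "high"
    else if (z >= config$z_marginal) "marginal"
    else "failed"
  rescue <- quality_class == "marginal" && median_neg > config$rescue_rlu
  structure(
    list(
      z_prime = z,
      quality_class = quality_class,
      passed = quality_class == "high" || rescue,
      rescue_applied = rescue
    ),
    class = "fpm_qc"
  )
}

#' Run quality control on one plate
#'
#' @param plate an `fpm_plate` with readout.
#' @param config pipeline thresholds from [fpm_config()].
#' @return an `fpm_qc` (see [classify_plate()]) with the plate's control
#'   statistics attached as `stats`.
#' @export
qc_plate <- function(plate, config = fpm_config()) {
  cs <- control_stats(plate)
  res <- classify_plate(z_prime(cs), cs$median_neg, config)
  res$stats <- cs
  res$plate_id <- plate$plate_id
  res$cancer_class <- plate$cancer_class
  res
}

#' @export
print.fpm_qc <- function(x, ...) {
  cat(sprintf("<fpm_qc%s> Z' = %.3f, %s, %s%s\n",
              if (!is.null(x$plate_id)) paste0(" ", x$plate_id) else "",
              x$z_prime, x$quality_class,
              if (x$passed) "passed" else "failed QC",
              if (x$rescue_applied) " (luminescence rescue)" else ""))
  invisible(x)
}

#' Cohort-level QC summary
#'
#' Pass counts and fractions per cancer-class stratum and overall, plus a
#' one-sample two-sided Wilcoxon test of the Z-prime scores against the 0.5
#' high-quality cutoff within each stratum.
#'
#' @param results list of `fpm_qc` objects (from [qc_plate()]).
#' @param strata optional character vector of stratum labels (defaults to the
#'   `cancer_class` recorded on each result).
#' @return list with `summary` (data.frame of counts and fractions) and
#'   `z_tests` (per-stratum `fpm_test` objects, `NULL` where n < 2).
#' @export
qc_cohort_summary <- function(results, strata = NULL) {
  if (length(results) == 0L) stop("no QC results supplied")
  passed <- vapply(results, function(r) r$passed, logical(1))
  z <- vapply(results, function(r) r$z_prime, numeric(1))
  if (is.null(strata)) {
    strata <- vapply(results, function(r) r$cancer_class %||% "all", character(1))
  }
  groups <- split(seq_along(results), strata)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(stratum = g, n = length(i), n_passed = sum(passed[i]),
               fraction = mean(passed[i]), percent = round(100 * mean(passed[i])),
               stringsAsFactors = FALSE)
  })
  overall <- data.frame(stratum = "overall", n = length(results),
                        n_passed = sum(passed), fraction = mean(passed),
                        percent = round(100 * mean(passed)), stringsAsFactors = FALSE)
  z_tests <- lapply(groups, function(i) {
    zi <- z[i]
    if (length(unique(zi)) < 2L) return(NULL)
    wt <- suppressWarnings(
      stats::wilcox.test(zi, mu = 0.5, alternative = "two.sided")
    )
    fpm_test(statistic = unname(wt$statistic), p_value = wt$p.value,
             method = "one-sample Wilcoxon vs Z' = 0.5", n = length(zi))
  })
  list(summary = rbind(do.call(rbind, rows), overall), z_tests = z_tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
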