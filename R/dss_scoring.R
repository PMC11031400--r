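# Drug sensitivity score (DSS): the area of the fitted inhibition curve
# above an activity threshold t, on the log10-concentration domain of the
# tested series, normalized to [<= 100]:
#
#   DSS = 100 * int_{x in [x_min, x_max]} max(min(y(x), y_cap) - t, 0) dx
#             / ((100 - t) * (x_max - x_min))
#
# Curves lying entirely below 0% inhibition (net proliferation) score the
# (negative) mean of the curve over the range instead, so that
# proliferation-inducing drugs are visible as DSS < 0. Curves that dip below
# zero but never clear the threshold score 0.

#' Scoring configuration
#'
#' @param t activity threshold in percent inhibition.
#' @param y_cap inhibition cap for integration.
#' @param effective_gt DSS above which a drug is classed effective.
#' @param ineffective_le DSS at or below which a drug is classed ineffective.
#' @return an `fpm_scoring_config` list.
#' @export
scoring_config <- function(t = 10, y_cap = 100, effective_gt = 10, ineffective_le = 0) {
  stopifnot(t > 0, t < y_cap, ineffective_le < effective_gt)
  structure(list(t = t, y_cap = y_cap, effective_gt = effective_gt,
                 ineffective_le = ineffective_le),
            class = "fpm_scoring_config")
}

# antiderivative of the 4PL on the log10 axis (numerically stable form)
fpl_antideriv <- function(x, bottom, top, m, hill) {
  u <- hill * (x - m)
  log_term <- ifelse(u > 0, u * log(10) + log1p(10^(-u)), log1p(10^u))
  bottom * x + (top - bottom) / (hill * log(10)) * log_term
}

#' Compute the drug sensitivity score of a fitted curve
#'
#' @param curve an `fpm_curve` from [fit_curve()].
#' @param config an `fpm_scoring_config`.
#' @param method `"closed_form"` integrates the log-logistic analytically
#'   (piecewise around the threshold/cap crossings); `"quadrature"` uses
#'   adaptive quadrature with absolute tolerance 1e-8 on the same branches.
#'   The two agree to ~1e-6 and serve as mutual cross-checks.
#' @return the DSS (dimensionless, at most 100).
#' @export
compute_dss <- function(curve, config = scoring_config(),
                        method = c("closed_form", "quadrature")) {
  stopifnot(inherits(curve, "fpm_curve"))
  method <- match.arg(method)
  pars <- c(curve$bottom, curve$top, curve$hill, curve$x_min, curve$x_max)
  if (!all(is.finite(pars))) stop("scoring error: non-finite curve parameters")
  t <- config$t; cap <- config$y_cap
  x_min <- curve$x_min; x_max <- curve$x_max
  dx <- x_max - x_min
  if (dx <= 0) stop("scoring error: empty concentration range")

  if (is.na(curve$ec50)) {               # flat curve
    y0 <- min(curve$top, cap)
    if (y0 > t) return(100 * (y0 - t) * dx / ((100 - t) * dx))
    if (y0 < 0) return(100 * y0 * dx / (100 * dx))
    return(0)
  }

  bottom <- curve$bottom; top <- curve$top
  m <- log10(curve$ec50); hill <- curve$hill
  yfun <- function(x) fpl_predict(x, bottom, top, m, hill)
  y_ends <- yfun(c(x_min, x_max))        # 4PL is monotone on x
  y_hi <- max(y_ends); y_lo <- min(y_ends)

  if (y_hi > t) {
    # split at the (single, by monotonicity) crossings of t and cap
    cuts <- c(fpl_solve(t, bottom, top, m, hill),
              fpl_solve(cap, bottom, top, m, hill))
    cuts <- cuts[!is.na(cuts) & cuts > x_min & cuts < x_max]
    xs <- sort(unique(c(x_min, cuts, x_max)))
    area <- 0
    for (i in seq_len(length(xs) - 1L)) {
      a <- xs[i]; b <- xs[i + 1L]
      ym <- yfun((a + b) / 2)
      if (ym <= t) next
      if (ym >= cap) {
        area <- area + (cap - t) * (b - a)
      } else if (method == "closed_form") {
        area <- area +
          fpl_antideriv(b, bottom, top, m, hill) -
          fpl_antideriv(a, bottom, top, m, hill) - t * (b - a)
      } else {
        area <- area + stats::integrate(function(z) yfun(z) - t, a, b,
                                        abs.tol = 1e-8, subdivisions = 200L)$value
      }
    }
    return(min(100 * area / ((100 - t) * dx), 100))
  }

  if (y_lo >= 0) return(0)
  if (y_hi < 0) {                        # entire curve below zero: proliferation
    area <- if (method == "closed_form") {
      fpl_antideriv(x_max, bottom, top, m, hill) -
        fpl_antideriv(x_min, bottom, top, m, hill)
    } else {
      stats::integrate(yfun, x_min, x_max, abs.tol = 1e-8, subdivisions = 200L)$value
    }
    return(100 * area / (100 * dx))
  }
  0
}

#' Fallback DSS from observed points when fitting failed
#'
#' Trapezoidal integration of the replicate-mean inhibition over the tested
#' log10 range, with the same threshold/cap/normalization branches as
#' [compute_dss()].
#'
#' @param x log10 concentration of each replicate point.
#' @param y percent inhibition of each replicate point.
#' @param config an `fpm_scoring_config`.
#' @return the fallback DSS.
#' @export
dss_from_points <- function(x, y, config = scoring_config()) {
  mu <- tapply(y, x, mean)
  xs <- as.numeric(names(mu))
  o <- order(xs)
  xs <- xs[o]; mu <- as.numeric(mu)[o]
  if (length(xs) < 2L) stop("scoring error: need >= 2 concentrations")
  t <- config$t; cap <- config$y_cap
  dx <- diff(range(xs))
  ybar <- pmin(mu, cap)
  trap <- function(v) sum(diff(xs) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  if (max(ybar) > t) {
    return(100 * trap(pmax(ybar - t, 0)) / ((100 - t) * dx))
  }
  if (min(ybar) >= 0) return(0)
  if (max(ybar) < 0) return(100 * trap(ybar) / (100 * dx))
  0
}

#' Effectiveness class of a DSS
#'
#' Effective when DSS exceeds 10, moderately effective in (0, 10], and
#' ineffective at or below 0 (a drug with no area above the activity
#' threshold has no measured effect).
#'
#' @param dss numeric vector of scores.
#' @param config an `fpm_scoring_config`.
#' @return character vector of classes.
#' @export
classify_effectiveness <- function(dss, config = scoring_config()) {
  stopifnot(all(is.finite(dss)))
  ifelse(dss > config$effective_gt, "effective",
         ifelse(dss > config$ineffective_le, "moderately_effective", "ineffective"))
}

#' Score a set of fitted curves against the drug library
#'
#' @param curves named list of `fpm_curve` (or `NULL` for unfittable series)
#'   as returned by [fit_plate()].
#' @param drug_library data.frame from [read_drug_library()] (may be `NULL`).
#' @param config an `fpm_scoring_config`.
#' @param qc_passed did the source plate pass QC.
#' @param fallback_points optional named list of data.frames (`x`,
#'   `inhibition`) for drugs whose fit is missing, scored by
#'   [dss_from_points()].
#' @return data.frame with one row per drug: `drug_id`, `dss`, `ic50_abs_uM`,
#'   `effectiveness_class`, `cmax_uM`, `formulary`, `actionable`,
#'   `qc_passed`, `fallback`.
#' @export
score_drugs <- function(curves, drug_library = NULL, config = scoring_config(),
                        qc_passed = TRUE, fallback_points = NULL) {
  if (length(curves) == 0L) stop("no curves to score")
  rows <- lapply(names(curves), function(id) {
    cv <- curves[[id]]
    if (!is.null(cv)) {
      dss <- compute_dss(cv, config)
      ic50 <- cv$ic50_abs
      fb <- FALSE
    } else if (!is.null(fallback_points[[id]])) {
      dss <- dss_from_points(fallback_points[[id]]$x, fallback_points[[id]]$inhibition, config)
      ic50 <- NA_real_
      fb <- TRUE
    } else {
      return(NULL)
    }
    cmax <- NA_real_; formulary <- NA
    if (!is.null(drug_library)) {
      j <- match(id, drug_library$drug_id)
      if (!is.na(j)) {
        cmax <- drug_library$cmax_uM[j]
        formulary <- drug_library$formulary[j]
      }
    }
    data.frame(drug_id = id, dss = dss, ic50_abs_uM = ic50,
               effectiveness_class = classify_effectiveness(dss, config),
               cmax_uM = cmax, formulary = formulary,
               actionable = gate_actionable(ic50, cmax),
               qc_passed = qc_passed, fallback = fb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-patient summary of drug results
#'
#' @param results data.frame from [score_drugs()].
#' @return list with class `counts` and `percents`, `n_tested`, and
#'   `waterfall` (results ordered by descending DSS, for plotting).
#' @export
patient_summary <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no drug results")
  cls <- factor(results$effectiveness_class,
                levels = c("effective", "moderately_effective", "ineffective"))
  counts <- table(cls)
  list(
    n_tested = nrow(results),
    counts = as.integer(counts),
    classes = names(counts),
    percents = 100 * as.integer(counts) / nrow(results),
    waterfall = results[order(-results$dss, results$drug_id), , drop = FALSE]
  )
}

#' Concordance of repeated drug sensitivity tests
#'
#' Spearman rank correlation of DSS (and optionally IC50) across repeated
#' screens of the same patient.
#'
#' @param dss1,dss2 paired DSS vectors from the two repeats.
#' @param ic50_1,ic50_2 optional paired IC50 vectors.
#' @return list of `fpm_test` objects (`dss`, and `ic50` when supplied).
#' @export
repeat_concordance <- function(dss1, dss2, ic50_1 = NULL, ic50_2 = NULL) {
  if (length(dss1) != length(dss2)) stop("repeat vectors must be paired")
  if (length(dss1) < 5L) stop("insufficient data: need >= 5 repeated pairs")
  out <- list(dss = spearman_test(dss1, dss2))
  if (!is.null(ic50_1)) {
    keep <- is.finite(ic50_1) & is.finite(ic50_2)
    if (sum(keep) >= 5L) out$ic50 <- spearman_test(ic50_1[keep], ic50_2[keep])
  }
  out
}
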