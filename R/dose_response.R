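# Control-anchored normalization and 4-parameter log-logistic (4PL) fitting.
#
# Inhibition is expressed on the percent scale anchored at the plate's own
# controls: 0% at the DMSO (negative) mean, 100% at the benzethonium
# (positive) mean. Values below 0 represent drug-induced proliferation and
# are deliberately not clipped.

#' Normalize a plate's drug wells to percent inhibition
#'
#' For a drug well with luminescence `L`, inhibition is
#' `y = 100 * (mu_n - L) / (mu_n - mu_p)` using that plate's control means.
#'
#' @param plate an `fpm_plate` with readout.
#' @param stats optional `fpm_control_stats` (recomputed from the plate when
#'   missing).
#' @return data.frame of drug wells with added columns `x`
#'   (log10 concentration in uM) and `inhibition` (percent).
#' @export
normalize_plate <- function(plate, stats = NULL) {
  stopifnot(inherits(plate, "fpm_plate"))
  if (is.null(stats)) stats <- control_stats(plate)
  if (stats$mu_n == stats$mu_p) {
    stop("undefined separation: positive and negative control means are equal")
  }
  dd <- plate$wells[plate$wells$content == "drug_dose" & !is.na(plate$wells$rlu), , drop = FALSE]
  dd$x <- log10(dd$concentration_uM)
  dd$inhibition <- 100 * (stats$mu_n - dd$rlu) / (stats$mu_n - stats$mu_p)
  rownames(dd) <- NULL
  dd
}

# 4PL model on the log10-concentration axis:
#   y(x) = bottom + (top - bottom) / (1 + 10^(hill * (m - x))),  m = log10(ec50)
fpl_predict <- function(x, bottom, top, m, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (m - x)))
}

# x where the 4PL attains inhibition level `level`; NA when never attained
fpl_solve <- function(level, bottom, top, m, hill) {
  if (top == bottom) return(NA_real_)
  r <- (level - bottom) / (top - level)
  if (!is.finite(r) || r <= 0) return(NA_real_)
  m + log10(r) / hill
}

#' Fit a 4-parameter log-logistic curve to replicate inhibition points
#'
#' Bounded least squares over all replicate points (replicates are not
#' averaged), minimized with Levenberg-Marquardt from a deterministic
#' multi-start grid of EC50 seeds spanning the tested range; the best fit is
#' the one with the lowest residual sum of squares, ties broken by the
#' smaller EC50. Bounds: bottom in \[-100, 50\], top in \[-100, 150\],
#' log10(ec50) in \[x_min - 1, x_max + 1\], hill in (0, 10\].
#'
#' The absolute IC50 (`ic50_abs`) is the concentration where the fitted curve
#' crosses 50% inhibition, reported only when it falls inside the admissible
#' EC50 range; it is the potency compared against Cmax downstream.
#'
#' @param x log10 concentration (uM) of each replicate point.
#' @param y percent inhibition of each replicate point.
#' @param n_starts number of EC50 seeds.
#' @return an `fpm_curve`: `bottom`, `top`, `ec50` (uM), `hill`, `rss`,
#'   `converged`, `ic50_abs` (uM or `NA`), `x_min`, `x_max`, `n_points`.
#' @export
fit_curve <- function(x, y, n_starts = 5L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4L) {
    stop("insufficient data: need >= 4 distinct concentrations")
  }
  x_min <- min(x); x_max <- max(x)

  if (stats::sd(y) == 0) {
    # degenerate flat data: exact flat fit
    return(new_curve(bottom = y[1L], top = y[1L], m = NA_real_, hill = 1,
                     rss = 0, converged = TRUE, x_min = x_min, x_max = x_max,
                     n = length(x)))
  }

  lower <- c(bottom = -100, top = -100, m = x_min - 1, hill = 1e-3)
  upper <- c(bottom = 50, top = 150, m = x_max + 1, hill = 10)
  start_bottom <- min(max(min(y), lower["bottom"]), upper["bottom"])
  start_top <- min(max(max(y), lower["top"]), upper["top"])
  seeds <- seq(x_min, x_max, length.out = n_starts)

  residual_fn <- function(p) fpl_predict(x, p[1L], p[2L], p[3L], p[4L]) - y
  best <- NULL
  for (m0 in seeds) {
    # iteration-limit chatter is expected for unidentifiable (near-flat)
    # series; convergence is judged on the residuals instead
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(start_bottom, start_top, m0, 1),
        lower = unname(lower), upper = unname(upper), fn = residual_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15, maxfev = 5000)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    p <- fit$par
    rss <- sum(residual_fn(p)^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && p[3L] < best$m)) {
      best <- list(bottom = p[1L], top = p[2L], m = p[3L], hill = p[4L], rss = rss)
    }
  }

  if (is.null(best)) {
    # optimization failed everywhere: fall back to the flat summary
    mu <- mean(y)
    return(new_curve(bottom = mu, top = mu, m = NA_real_, hill = 1,
                     rss = sum((y - mu)^2), converged = FALSE,
                     x_min = x_min, x_max = x_max, n = length(x)))
  }
  # never report a fit worse than the flat model (nested-model guard)
  flat_rss <- sum((y - mean(y))^2)
  if (best$rss > flat_rss) {
    mu <- mean(y)
    return(new_curve(bottom = mu, top = mu, m = NA_real_, hill = 1,
                     rss = flat_rss, converged = TRUE,
                     x_min = x_min, x_max = x_max, n = length(x)))
  }
  new_curve(bottom = best$bottom, top = best$top, m = best$m, hill = best$hill,
            rss = best$rss, converged = TRUE, x_min = x_min, x_max = x_max,
            n = length(x))
}

new_curve <- function(bottom, top, m, hill, rss, converged, x_min, x_max, n) {
  ic50 <- NA_real_
  if (!is.na(m)) {
    x50 <- fpl_solve(50, bottom, top, m, hill)
    if (!is.na(x50) && x50 >= x_min - 1 && x50 <= x_max + 1) ic50 <- 10^x50
  } else if (bottom == top && bottom == 50) {
    ic50 <- NA_real_  # flat at exactly 50%: no unique crossing
  }
  structure(
    list(bottom = bottom, top = top, ec50 = if (is.na(m)) NA_real_ else 10^m,
         hill = hill, rss = rss, converged = converged, ic50_abs = ic50,
         x_min = x_min, x_max = x_max, n_points = n),
    class = "fpm_curve"
  )
}

#' Evaluate a fitted curve at log10 concentrations
#' @param curve an `fpm_curve`.
#' @param x log10 concentration (uM).
#' @return percent inhibition.
#' @export
curve_predict <- function(curve, x) {
  stopifnot(inherits(curve, "fpm_curve"))
  if (is.na(curve$ec50)) return(rep(curve$top, length(x)))
  fpl_predict(x, curve$bottom, curve$top, log10(curve$ec50), curve$hill)
}

#' @export
print.fpm_curve <- function(x, ...) {
  cat(sprintf(
    "<fpm_curve> bottom %.2f, top %.2f, EC50 %s uM, hill %.3f, rss %.4g%s, IC50 %s uM\n",
    x$bottom, x$top, if (is.na(x$ec50)) "NA" else format(x$ec50, digits = 4),
    x$hill, x$rss, if (x$converged) "" else " (not converged)",
    if (is.na(x$ic50_abs)) "NA" else format(x$ic50_abs, digits = 4)
  ))
  invisible(x)
}

#' Fit all dose series on a normalized plate
#'
#' @param plate an `fpm_plate` with readout.
#' @param config pipeline thresholds (controls the QC override).
#' @param allow_failed_qc fit even when the plate fails QC.
#' @return named list of `fpm_curve` (drugs with insufficient series are
#'   returned as `NULL` entries, preserving the drug name).
#' @export
fit_plate <- function(plate, config = fpm_config(), allow_failed_qc = FALSE) {
  qc <- qc_plate(plate, config)
  if (!qc$passed && !allow_failed_qc) {
    stop("plate ", plate$plate_id, " failed QC; pass allow_failed_qc = TRUE to override")
  }
  pts <- normalize_plate(plate, qc$stats)
  series <- extract_dose_series(plate)
  out <- lapply(series, function(s) {
    sp <- pts[pts$drug_id == s$drug_id, , drop = FALSE]
    if (s$insufficient || length(unique(sp$x)) < 4L) return(NULL)
    fit_curve(sp$x, sp$inhibition)
  })
  names(out) <- vapply(series, function(s) s$drug_id, character(1))
  out
}
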