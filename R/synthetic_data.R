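# Seeded synthetic-data generators: 384-well screen plates with the
# duplicate 10-point dose design, on-plate DMSO / benzethonium controls and
# multiplicative log-normal noise; whole screens; and clinical cohorts in
# which PFS and response are monotonically coupled to the administered
# drug's sensitivity. Ground-truth latent parameters are emitted for
# recovery tests.

#' Simulation configuration
#'
#' Defaults mirror the screening design being emulated: duplicate 10-point
#' dose series from 10 uM down to 0.5 nM per drug, DMSO negative and
#' benzethonium positive control wells, negative-control mean 100,000 RLU at
#' 5% CV and positive-control mean 2,000 RLU at 10% CV (typical
#' CellTiter-Glo scales; the rescue threshold of 5,000 RLU is cleared by
#' construction), and a 10% plate failure rate realized as collapsed
#' control separation.
#'
#' @param seed integer seed; every generator call is deterministic given it.
#' @param n_patients cohort size.
#' @param n_guided,n_tpc patients assigned to the FPM-guided and
#'   treatment-of-physician's-choice cohorts among those treated.
#' @param n_drugs drugs per screen (at most 16 fit on one 384-well plate
#'   alongside 32 control wells).
#' @param sens_frac fractions of sensitive / moderately sensitive / resistant
#'   drugs per patient (sums to 1).
#' @param neg_mean,neg_cv,pos_mean,pos_cv control-well model (RLU,
#'   coefficient of variation).
#' @param well_cv multiplicative log-normal noise CV of drug wells.
#' @param plate_failure_rate probability a plate fails (collapsed control
#'   separation with inflated variance).
#' @param pfs_intercept,pfs_slope,pfs_sd linear outcome coupling
#'   `PFS_weeks = intercept + slope * DSS_administered + noise`.
#' @param response_threshold latent-benefit threshold (on the
#'   `slope * DSS + noise` scale) above which the best response is objective
#'   (PR or better).
#' @return an `fpm_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_patients = 25L, n_guided = 6L, n_tpc = 8L,
                       n_drugs = 16L,
                       sens_frac = c(sensitive = 0.15, moderate = 0.11, resistant = 0.74),
                       neg_mean = 1e5, neg_cv = 0.05,
                       pos_mean = 2e3, pos_cv = 0.10,
                       well_cv = 0.05,
                       plate_failure_rate = 0.10,
                       pfs_intercept = 10, pfs_slope = 1.0, pfs_sd = 8,
                       response_threshold = 25) {
  stopifnot(abs(sum(sens_frac) - 1) < 1e-9, all(sens_frac >= 0),
            neg_cv >= 0, pos_cv >= 0, well_cv >= 0,
            plate_failure_rate >= 0, plate_failure_rate <= 1,
            n_guided + n_tpc <= n_patients)
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         n_guided = as.integer(n_guided), n_tpc = as.integer(n_tpc),
         n_drugs = as.integer(n_drugs), sens_frac = sens_frac,
         neg_mean = neg_mean, neg_cv = neg_cv,
         pos_mean = pos_mean, pos_cv = pos_cv, well_cv = well_cv,
         plate_failure_rate = plate_failure_rate,
         pfs_intercept = pfs_intercept, pfs_slope = pfs_slope, pfs_sd = pfs_sd,
         response_threshold = response_threshold),
    class = "fpm_sim_config"
  )
}

# the tested series: ten half-log-ish points from 0.5 nM to 10 uM
default_concentrations <- function() {
  10^seq(log10(5e-4), log10(10), length.out = 10)
}

# log-normal multiplier with unit mean and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Latent drug-response profile for one patient
#'
#' Draws each drug's true 4PL parameters from the configured sensitivity
#' mixture: sensitive drugs have low EC50 (log-normal around 0.05 uM) and
#' near-complete kill, moderately sensitive drugs have mid-range EC50 around
#' 1 uM and partial maximal inhibition, resistant drugs have little or no
#' inhibition in the tested range.
#'
#' @param config an `fpm_sim_config`.
#' @param n_drugs number of drugs (defaults to the configured count).
#' @param drug_ids optional drug names.
#' @return data.frame: `drug_id`, `class`, `bottom`, `top`, `ec50_uM`,
#'   `hill`, plus the latent `dss_true` implied by the noise-free curve over
#'   the tested range.
#' @export
simulate_patient_profile <- function(config, n_drugs = config$n_drugs,
                                     drug_ids = sprintf("drug%02d", seq_len(n_drugs))) {
  cls <- sample(names(config$sens_frac), n_drugs, replace = TRUE,
                prob = config$sens_frac)
  ec50 <- ifelse(cls == "sensitive", stats::rlnorm(n_drugs, log(0.05), 0.6),
          ifelse(cls == "moderate", stats::rlnorm(n_drugs, log(0.8), 0.5),
                 stats::rlnorm(n_drugs, log(50), 0.8)))
  top <- ifelse(cls == "sensitive", stats::runif(n_drugs, 85, 100),
         ifelse(cls == "moderate", stats::runif(n_drugs, 25, 55),
                stats::runif(n_drugs, 0, 8)))
  hill <- stats::runif(n_drugs, 0.8, 2)
  prof <- data.frame(drug_id = drug_ids, class = cls, bottom = 0, top = top,
                     ec50_uM = ec50, hill = hill, stringsAsFactors = FALSE)
  conc <- default_concentrations()
  prof$dss_true <- vapply(seq_len(n_drugs), function(i) {
    cv <- new_curve(bottom = 0, top = prof$top[i], m = log10(prof$ec50_uM[i]),
                    hill = prof$hill[i], rss = 0, converged = TRUE,
                    x_min = log10(min(conc)), x_max = log10(max(conc)),
                    n = 20L)
    compute_dss(cv)
  }, numeric(1))
  prof
}

#' Simulate one 384-well assay plate
#'
#' Lays out duplicate 10-point series for each drug (row-major), 16 DMSO
#' negative and 16 benzethonium positive control wells, draws controls from
#' the control model and drug wells from the patient's latent log-logistic
#' response mapped onto the control scale
#' (`mu_n - (mu_n - mu_p) * y/100`) with multiplicative log-normal noise.
#' Output is byte-identical for identical seeds.
#'
#' @param config an `fpm_sim_config`.
#' @param profile data.frame from [simulate_patient_profile()].
#' @param patient_id,plate_id identifiers.
#' @param failed force the plate failure mode (`NA` draws it from
#'   `plate_failure_rate`).
#' @param seed optional seed override (defaults to `config$seed`).
#' @param received_date,readout_date plate dates.
#' @return an `fpm_plate`.
#' @export
simulate_plate <- function(config, profile, patient_id = "patient1",
                           plate_id = "plate1", failed = NA, seed = config$seed,
                           received_date = as.Date("2026-01-05"),
                           readout_date = received_date + 6) {
  n_drugs <- nrow(profile)
  conc <- default_concentrations()
  n_needed <- n_drugs * 2L * length(conc) + 32L
  if (n_needed > 384L) stop("capacity exceeded: ", n_needed, " wells needed")
  set.seed(seed)
  if (is.na(failed)) failed <- stats::runif(1) < config$plate_failure_rate

  addr <- paste0(rep(PLATE_ROWS, each = 24), rep(PLATE_COLS, times = 16))
  k <- 0L
  take <- function(n) { w <- addr[(k + 1L):(k + n)]; k <<- k + n; w }

  drug_rows <- do.call(rbind, lapply(seq_len(n_drugs), function(i) {
    data.frame(well = take(2L * length(conc)),
               content = "drug_dose", drug_id = profile$drug_id[i],
               concentration_uM = rep(conc, each = 2L),
               replicate = rep(1:2, times = length(conc)),
               stringsAsFactors = FALSE)
  }))
  ctrl_rows <- data.frame(
    well = take(32L),
    content = rep(c("negative_control", "positive_control"), each = 16L),
    drug_id = NA_character_, concentration_uM = NA_real_, replicate = 1L,
    stringsAsFactors = FALSE
  )
  n_empty <- 384L - nrow(drug_rows) - 32L
  empty_rows <- if (n_empty > 0L) data.frame(
    well = take(n_empty), content = "empty", drug_id = NA_character_,
    concentration_uM = NA_real_, replicate = 1L, stringsAsFactors = FALSE
  )
  layout <- rbind(drug_rows, ctrl_rows, empty_rows)

  # control model; a failed plate collapses the separation and inflates
  # the control variance so that Z' drops below the marginal band
  if (failed) {
    pos_mean <- config$neg_mean * 0.55
    pos_cv <- max(config$pos_cv, 0.45)
    neg_cv <- max(config$neg_cv, 0.45)
  } else {
    pos_mean <- config$pos_mean
    pos_cv <- config$pos_cv
    neg_cv <- config$neg_cv
  }
  rlu <- numeric(nrow(layout))
  neg_i <- layout$content == "negative_control"
  pos_i <- layout$content == "positive_control"
  rlu[neg_i] <- config$neg_mean * rlnorm_cv(sum(neg_i), neg_cv)
  rlu[pos_i] <- pos_mean * rlnorm_cv(sum(pos_i), pos_cv)

  dd <- layout$content == "drug_dose"
  j <- match(layout$drug_id[dd], profile$drug_id)
  y <- fpl_predict(log10(layout$concentration_uM[dd]),
                   profile$bottom[j], profile$top[j],
                   log10(profile$ec50_uM[j]), profile$hill[j])
  signal <- config$neg_mean - (config$neg_mean - config$pos_mean) * y / 100
  rlu[dd] <- pmax(signal, 0) * rlnorm_cv(sum(dd), config$well_cv)
  rlu[layout$content == "empty"] <- NA_real_
  layout$rlu <- rlu

  fpm_plate(layout, plate_id = plate_id, patient_id = patient_id,
            cancer_class = "solid", received_date = received_date,
            readout_date = readout_date)
}

#' Simulate a full cohort: screens plus coupled clinical outcomes
#'
#' Each patient receives a latent drug profile and one screen plate. Treated
#' patients are split into an FPM-guided cohort (administered drug = the
#' patient's highest-latent-DSS drug) and a TPC cohort (a randomly chosen
#' drug, emulating physician's choice unguided by the screen). Current PFS
#' follows the configured linear coupling to the administered drug's latent
#' DSS; the best objective response is driven by the same latent benefit
#' against `response_threshold`. Previous-regimen PFS and response are drawn
#' from a common refractory baseline, uncoupled to the screen.
#'
#' @param config an `fpm_sim_config`.
#' @param include_plates generate the screen plates (set `FALSE` for
#'   outcome-level simulation studies, which only need the latent profiles).
#' @return list: `plates` (per patient; empty when `include_plates = FALSE`),
#'   `profiles` (ground-truth latent parameters), `outcomes` (a
#'   [read_outcomes()]-shaped data.frame with `treatment_dss` set to the
#'   administered drug's latent DSS), and `administered` (per-patient
#'   administered drug).
#' @export
simulate_cohort <- function(config = sim_config(), include_plates = TRUE) {
  set.seed(config$seed)
  ids <- sprintf("EVS%03d", seq_len(config$n_patients))
  profile_seeds <- sample.int(2^30, config$n_patients)
  plate_seeds <- sample.int(2^30, config$n_patients)
  treated <- seq_len(config$n_guided + config$n_tpc)
  cohort <- rep(NA_character_, config$n_patients)
  cohort[treated] <- rep(c("FPM_guided", "TPC"), c(config$n_guided, config$n_tpc))

  profiles <- list(); plates <- list(); rows <- list(); administered <- list()
  for (i in seq_len(config$n_patients)) {
    set.seed(profile_seeds[i])
    prof <- simulate_patient_profile(config)
    profiles[[ids[i]]] <- prof
    if (include_plates) {
      plates[[ids[i]]] <- simulate_plate(
        config, prof, patient_id = ids[i],
        plate_id = paste0(ids[i], "-P1"), seed = plate_seeds[i],
        received_date = as.Date("2026-01-05") + (i - 1L) * 7L
      )
    }
    if (is.na(cohort[i])) next

    set.seed(profile_seeds[i] + 1L)
    drug <- if (cohort[i] == "FPM_guided") {
      prof$drug_id[which.max(prof$dss_true)]
    } else {
      sample(prof$drug_id, 1L)
    }
    dss_admin <- prof$dss_true[prof$drug_id == drug]
    benefit <- config$pfs_slope * dss_admin + stats::rnorm(1, 0, config$pfs_sd)
    current_pfs <- max(config$pfs_intercept + benefit, 1)
    responder <- benefit > config$response_threshold
    prev_pfs <- stats::rlnorm(1, log(12), 0.6)
    prev_resp <- sample(c("PD", "SD", "PR"), 1L, prob = c(0.6, 0.3, 0.1))
    administered[[ids[i]]] <- drug
    rows[[ids[i]]] <- data.frame(
      patient_id = ids[i], cohort = cohort[i],
      prev_response = prev_resp,
      current_response = if (responder) "PR" else sample(c("SD", "PD"), 1L),
      prev_pfs_weeks = round(prev_pfs, 1),
      current_pfs_weeks = round(current_pfs, 1),
      censored = FALSE,
      treatment_dss = dss_admin,
      stringsAsFactors = FALSE
    )
  }
  list(plates = plates, profiles = profiles,
       outcomes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       administered = administered, config = config)
}

#' Synthetic drug library with clinically plausible Cmax values
#'
#' @param drug_ids drug identifiers to cover.
#' @param seed generator seed.
#' @param cmax_meanlog,cmax_sdlog log-normal Cmax model (uM); the default
#'   centers on ~2 uM, the scale of typical oncology plasma exposures.
#' @param frac_no_cmax fraction of drugs lacking a pharmacokinetic reference
#'   (their Cmax is absent, so they can never be auto-recommended).
#' @return data.frame in the [read_drug_library()] layout.
#' @export
synthetic_drug_library <- function(drug_ids, seed = 1L,
                                   cmax_meanlog = log(2), cmax_sdlog = 1,
                                   frac_no_cmax = 0.1) {
  set.seed(seed)
  n <- length(drug_ids)
  cmax <- stats::rlnorm(n, cmax_meanlog, cmax_sdlog)
  cmax[stats::runif(n) < frac_no_cmax] <- NA_real_
  data.frame(
    drug_id = drug_ids,
    name = drug_ids,
    class = sample(c("cytotoxic", "kinase_inhibitor", "epigenetic", "repurposed"),
                   n, replace = TRUE),
    formulary = stats::runif(n) < 0.5,
    cmax_uM = cmax,
    stringsAsFactors = FALSE
  )
}

#' Write the packaged micro-fixtures used by tests and documentation
#'
#' Writes, under `dir`: `orr_2x2.csv` (the objective-response counts of a
#' 6-vs-8 two-cohort comparison with 5 and 1 responders), a noise-free flat
#' plate (`flat_plate_layout.csv` / `flat_plate_readout.csv`, every drug
#' inactive so all DSS are 0), and a QC-failing plate
#' (`qc_fail_layout.csv` / `qc_fail_readout.csv`).
#'
#' @param dir output directory (created if needed).
#' @param seed generator seed.
#' @return invisibly, the paths written.
#' @export
fixture_suite <- function(dir, seed = 20260101L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  orr <- data.frame(cohort = c("FPM_guided", "TPC"), responders = c(5L, 1L),
                    n = c(6L, 8L))
  p <- file.path(dir, "orr_2x2.csv")
  utils::write.csv(orr, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  cfg <- sim_config(seed = seed, n_drugs = 4L, well_cv = 0,
                    neg_cv = 0.02, pos_cv = 0.02, plate_failure_rate = 0)
  prof <- data.frame(drug_id = sprintf("drug%02d", 1:4), class = "resistant",
                     bottom = 0, top = 0, ec50_uM = 1, hill = 1,
                     dss_true = 0, stringsAsFactors = FALSE)
  flat <- simulate_plate(cfg, prof, patient_id = "FIX1", plate_id = "flat",
                         failed = FALSE, seed = seed)
  write_plate(flat, file.path(dir, "flat_plate_layout.csv"),
              file.path(dir, "flat_plate_readout.csv"))
  paths <- c(paths, file.path(dir, c("flat_plate_layout.csv", "flat_plate_readout.csv")))

  qcf <- simulate_plate(cfg, prof, patient_id = "FIX2", plate_id = "qcfail",
                        failed = TRUE, seed = seed + 1L)
  write_plate(qcf, file.path(dir, "qc_fail_layout.csv"),
              file.path(dir, "qc_fail_readout.csv"))
  paths <- c(paths, file.path(dir, c("qc_fail_layout.csv", "qc_fail_readout.csv")))
  invisible(paths)
}
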