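#!/usr/bin/env Rscript
# Step 5: does the screen predict the clinic?
#
# On the simulated treated cohort: Spearman correlation of the administered
# drug's DSS with current PFS, and ROC analysis of DSS against objective
# response with the Youden-optimal DSS cutoff and its confusion metrics.

suppressPackageStartupMessages(library(fpmdst))

sim <- simulate_cohort(sim_config(seed = 20260405), include_plates = FALSE)
out <- sim$outcomes
responder <- out$current_response %in% c("CR", "PR")

sp <- spearman_test(out$treatment_dss, out$current_pfs_weeks)
cat(sprintf("Spearman DSS vs PFS: rho = %.4f, P = %.4g (n = %d)\n",
            sp$statistic, sp$p_value, sp$n))

if (any(responder) && !all(responder)) {
  rc <- roc_cutoff(out$treatment_dss, responder)
  cat(sprintf("ROC AUC = %.3f; optimal cutoff DSS > %.2f\n", rc$auc, rc$optimal_cutoff))
  cat(sprintf("  accuracy %.3f, PPV %.3f, NPV %.3f, recall %.3f, MCC %.3f, F1 %.3f\n",
              rc$accuracy, rc$ppv, rc$npv, rc$recall, rc$mcc, rc$f1))
  write.csv(data.frame(spearman_rho = sp$statistic, spearman_p = sp$p_value,
                       auc = rc$auc, cutoff = rc$optimal_cutoff,
                       accuracy = rc$accuracy, ppv = rc$ppv, npv = rc$npv,
                       recall = rc$recall, mcc = rc$mcc, f1 = rc$f1),
            "results/dss_prediction.csv", row.names = FALSE)
  cat("Wrote results/dss_prediction.csv\n")
} else {
  cat("Single-class responses in this draw; ROC analysis not applicable.\n")
}
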