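#!/usr/bin/env Rscript
# Step 2: per-plate Z-prime quality control.
#
# Every plate is scored from its on-plate controls: high quality at
# Z' >= 0.5, marginal in [-0.5, 0.5) (passing only when the median DMSO
# luminescence exceeds 5,000 RLU), failed below -0.5. Reports pass counts
# per cancer class with a one-sample Wilcoxon of Z' against the 0.5 cutoff.

suppressPackageStartupMessages(library(fpmdst))

coh <- simulate_cohort(sim_config(seed = 20260405))
qcs <- lapply(coh$plates, qc_plate)

qc_table <- data.frame(
  plate_id = vapply(qcs, `[[`, "", "plate_id"),
  z_prime = round(vapply(qcs, `[[`, 0, "z_prime"), 4),
  quality_class = vapply(qcs, `[[`, "", "quality_class"),
  passed = vapply(qcs, `[[`, TRUE, "passed"),
  rescue_applied = vapply(qcs, `[[`, TRUE, "rescue_applied")
)
write.csv(qc_table, "results/qc_plates.csv", row.names = FALSE)

summ <- qc_cohort_summary(qcs)
write.csv(summ$summary, "results/qc_summary.csv", row.names = FALSE)

ov <- summ$summary[summ$summary$stratum == "overall", ]
cat(sprintf("QC pass rate: %d of %d plates (%.1f%%).\n",
            ov$n_passed, ov$n, 100 * ov$fraction))
for (g in names(summ$z_tests)) {
  zt <- summ$z_tests[[g]]
  if (!is.null(zt)) {
    cat(sprintf("  %s: median Z' = %.3f vs 0.5, Wilcoxon P = %.4g (n = %d)\n",
                g, median(qc_table$z_prime[qc_table$passed]), zt$p_value, zt$n))
  }
}
cat("Wrote results/qc_plates.csv, qc_summary.csv\n")
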