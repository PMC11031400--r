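#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# 25 enrolled patients screened against a 16-drug library in duplicate
# 10-point dose series (10 uM .. 0.5 nM) on 384-well plates with DMSO /
# benzethonium controls and a 10% plate-failure rate. Among treated
# patients, 6 are FPM-guided (treated with their top-scoring drug) and 8
# receive physician's choice. Writes the screen inputs consumed by the
# later steps.

suppressPackageStartupMessages(library(fpmdst))

cfg <- sim_config(seed = 20260405)
coh <- simulate_cohort(cfg)
lib <- synthetic_drug_library(sprintf("drug%02d", seq_len(cfg$n_drugs)),
                              seed = cfg$seed)

dir.create("results", showWarnings = FALSE)
write.csv(lib, "results/drug_library.csv", row.names = FALSE)
write.csv(coh$outcomes, "results/simulated_outcomes.csv", row.names = FALSE)

truth <- do.call(rbind, lapply(names(coh$profiles), function(id) {
  cbind(patient_id = id, coh$profiles[[id]])
}))
write.csv(truth, "results/latent_profiles.csv", row.names = FALSE)

# one example plate in the on-disk CSV dialect
write_plate(coh$plates[[1]], "results/example_plate_layout.csv",
            "results/example_plate_readout.csv",
            "results/example_plate_meta.csv")

cat(sprintf("Simulated %d patients (%d FPM-guided, %d TPC treated), %d plates.\n",
            cfg$n_patients, cfg$n_guided, cfg$n_tpc, length(coh$plates)))
cat(sprintf("Median latent-effective drugs per patient: %.0f of %d tested.\n",
            median(vapply(coh$profiles, function(p) sum(p$dss_true > 10), 0)),
            cfg$n_drugs))
cat("Wrote results/drug_library.csv, simulated_outcomes.csv, latent_profiles.csv, example_plate_*.csv\n")
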