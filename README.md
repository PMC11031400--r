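# fpmdst

Functional precision medicine (FPM) programs screen a patient's own tumor
cells ex vivo against a library of approved drugs and return a ranked
treatment report to a tumor board within a clinically actionable window.
`fpmdst` implements that analysis end to end for 384-well luminescence
(ATP-viability) drug sensitivity testing (DST) of patient-derived tumor
cultures, together with the outcome statistics used to evaluate such
programs against each patient's own treatment history and a comparator
cohort. It is written for translational researchers running or evaluating
DST screens: plate ingestion, quality control, dose–response fitting, drug
scoring, report assembly and cohort statistics are all exposed as plain R
functions over data frames.

## What it computes

**Plate quality control.** Each plate carries DMSO negative and 100 µM
benzethonium chloride positive control wells. Assay quality is the Z′
factor

    Z' = 1 − 3 (σ_p + σ_n) / |µ_p − µ_n|

from the sample means and s.d. of the two control sets. Plates with
Z′ ≥ 0.5 are high quality; marginal plates (−0.5 ≤ Z′ < 0.5) pass only when
the median negative-control luminescence exceeds 5,000 RLU; plates below
−0.5 fail and contribute nothing downstream.

**Dose–response and DSS.** Well luminescence `L` is normalized to percent
inhibition `y = 100 (µ_n − L)/(µ_n − µ_p)` against that plate's own
controls, and each drug's duplicate 10-point series (10 µM … 0.5 nM) is fit
with a bounded 4-parameter log-logistic curve on the log10-concentration
axis,

    y(x) = bottom + (top − bottom) / (1 + 10^{h (log10 EC50 − x)}).

The drug sensitivity score integrates the fitted curve above a 10%
activity threshold t over the tested range [x_min, x_max], capped at 100%:

    DSS = 100 ∫ max(min(y, 100) − t, 0) dx / ((100 − t)(x_max − x_min)),

so DSS ≤ 100, inactive drugs score 0 and net-proliferative drugs score
below 0. Drugs are classed effective (DSS > 10), moderately effective
(0 < DSS ≤ 10) or ineffective (DSS ≤ 0), and are recommendable only when
the absolute IC50 (the 50%-inhibition crossing of the fitted curve) does
not exceed the drug's maximum clinically achievable plasma concentration
Cmax.

**Outcome statistics.** The feasibility endpoint (reports returned within
28 days) is tested with a one-sided exact binomial test against a 30% null
with its exact Clopper–Pearson interval. Objective-response and
PFS-ratio ≥ 1.3 comparisons between cohorts use Barnard's unconditional
exact test (pooled-score statistic, supremum over the nuisance success
probability on a 10⁻⁴ grid with refinement). Within-patient
progression-free survival (PFS) changes use the exact paired Wilcoxon test;
between-cohort PFS uses the logrank test; DSS–outcome coupling uses
Spearman correlation and a ROC analysis with the Youden-optimal DSS cutoff
and its confusion metrics.

A seeded synthetic-data module generates plates, screens and outcome-coupled
cohorts with the same design, so the whole pipeline runs and is testable
with no external data.

## Worked example

```r
library(fpmdst)

cfg <- sim_config(seed = 42, n_patients = 4, n_guided = 1, n_tpc = 1,
                  n_drugs = 8, plate_failure_rate = 0)
coh <- simulate_cohort(cfg)
lib <- synthetic_drug_library(sprintf("drug%02d", 1:8), seed = 42)
run <- run_pipeline(coh$plates, lib)
print(run)
#> <fpm_run 46a27884> 4 patients reported, 0 incomplete, 4 plates (4 passed QC)
print(run$reports[[1]])
#> <fpm_report EVS001> (solid) 1 recommendations; 1 effective / 2 moderate / 5 ineffective drugs; turnaround 6 days (within window)
#>  rank drug_id      dss ic50_abs_uM  cmax_uM formulary is_combination
#>     1  drug02 53.23383  0.03172997 1.137063     FALSE          FALSE
```

Patient EVS001's screen found one actionable recommendation: drug02 with a
DSS of 53.2 (strongly effective) and an IC50 of 0.032 µM, well below its
1.14 µM Cmax, reported 6 days after sample receipt. The other effective or
moderate drugs either never reached 50% inhibition or exceeded their Cmax
and are kept in the report annex for physician review.

The packaged 14-patient clinical outcomes table (6 FPM-guided vs 8
physician's-choice patients) reproduces the cohort comparison:

```r
out <- read_outcomes(system.file("extdata", "outcomes_table2.csv", package = "fpmdst"))
cc <- cohort_comparison(out)
print(cc$orr_barnard)
#> <fpm_test> Barnard unconditional test (two.sided): statistic 2.65, P = 0.01039 (n = 14)
```

Five of six guided patients versus one of eight comparator patients had an
objective response; Barnard's two-sided P = 0.0104 indicates the guided
cohort's response rate is unlikely under a common response probability.

## Analysis workflow

The numbered drivers under `analysis/` run the study analysis over a
simulated cohort and write their tables under `results/`:

1. `01_simulate_screens.R` — cohort, plates, drug library
2. `02_quality_control.R` — per-plate Z′ and pass fractions
3. `03_fit_and_score.R` — fits, DSS, reports, feasibility endpoint
4. `04_outcomes.R` — cohort outcome statistics (simulated + clinical table)
5. `05_dss_outcome_prediction.R` — Spearman DSS–PFS and ROC cutoff analysis

Run them in order with `Rscript analysis/01_simulate_screens.R`, etc.

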