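---
title: "Methods: ex vivo drug sensitivity testing and FPM outcome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex vivo drug sensitivity testing and FPM outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmdst)
```

`fpmdst` models a functional precision medicine (FPM) workflow for
relapsed/refractory cancers: short-term patient-derived tumor cultures are
screened ex vivo against a drug library on 384-well ATP-luminescence
plates, each drug's dose–response is summarized into a drug sensitivity
score (DSS), actionable drugs are ranked into a tumor-board report, and
the program is evaluated with feasibility and clinical-outcome statistics.
This vignette records the model, its assumptions, the tunable parameters
and the design choices made where the underlying conventions were
genuinely open.

## Plate model

A plate is a set of up to 384 wells (rows A–P, columns 1–24), each either
a drug well (drug, concentration in µM, replicate index), a DMSO negative
control, a benzethonium chloride positive control, or empty. The default
screen design tests each drug in duplicate at ten concentrations from
10 µM down to 0.5 nM, leaving room for 16 drugs plus 16 + 16 control wells
per plate. Files are comma-delimited UTF-8 with a header row; wells are
addressed "A1".."P24"; concentrations are always µM. Combinations are a
single drug identifier joining agent names with `+` in lexicographic order
(`combination_id()`), because a screen can only score the mixture it was
given; constituent attribution happens later in
`compare_combinations()`. Dates are ISO-8601; turnaround is whole days
with the receipt day as day 0.

## Quality control

Assay quality per plate is the Z′ factor,
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$, computed from the
sample (n−1) means and standard deviations of the positive and negative
control wells. Classes: high for $0.5 \le Z' \le 1$, marginal for
$-0.5 \le Z' < 0.5$, failed below. High plates pass; marginal plates pass
only when the median negative-control luminescence exceeds 5,000 RLU. Two
readings of that rescue rule were possible; we take "median luminescence"
to mean the median of the DMSO wells — the plate's signal ceiling — since
the rule exists to catch globally dead plates and only the negative
controls carry signal. Boundary handling is literal: $Z'$ exactly 0.5 is
high, exactly −0.5 is marginal, a median of exactly 5,000 fails. No
spatial or edge-effect correction is attempted (screens at this scale
typically pass or fail wholesale; see Non-goals below).

## Normalization and curve fitting

Inhibition anchors both controls: $y = 100(\mu_n - L)/(\mu_n - \mu_p)$, so
0% is the DMSO level and 100% the benzethonium kill level. Values are not
clipped: $y < 0$ encodes drug-induced proliferation, which is a real and
clinically meaningful screen outcome (e.g. steroid-driven blast
proliferation in leukemia samples), and must survive into the score.

The dose–response model is the 4-parameter log-logistic on the
$x = \log_{10}$ concentration axis,
$y(x) = b + (T - b)/(1 + 10^{h(m - x)})$ with $m = \log_{10} EC_{50}$.
The fit minimizes least squares over all replicate points (replicates are
never averaged — their spread is the only variance information available
at $n = 1$ biological replicate) with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`): $b \in [-100, 50]$, $T \in [-100, 150]$,
$m \in [x_{\min}-1, x_{\max}+1]$, $h \in (0, 10]$. Five deterministic
EC50 starts span the tested range; the lowest residual sum of squares
wins, ties resolve to the smaller EC50. A fit is never reported worse
than the flat model (the nested-model guard replaces it by the flat fit);
all-identical responses short-circuit to an exact flat fit. Iteration
caps are generous (500) because near-flat series are unidentifiable by
construction and simply keep their best bounded solution.

Two potencies are reported. The *relative* EC50 is the curve midpoint.
The *absolute* IC50 is where the fitted curve crosses 50% inhibition,
reported only inside the admissible range
$[10^{x_{\min}-1}, 10^{x_{\max}+1}]$ µM; it is the quantity compared to a
plasma concentration, because "half of this drug's own maximal effect"
(EC50) is not a clinical exposure statement.

## Drug sensitivity score

With $\bar y(x) = \min(y(x), y_{cap})$ and activity threshold $t$
(defaults $y_{cap} = 100$, $t = 10$):

$$\mathrm{DSS} = 100 \cdot
  \frac{\int_{x_{\min}}^{x_{\max}} \max(\bar y(x) - t,\, 0)\, dx}
       {(100 - t)(x_{\max} - x_{\min})}$$

when the curve exceeds $t$ anywhere; 0 when it never exceeds $t$ but stays
non-negative; and the (negative) mean of $\bar y$ over the range when the
entire curve lies below zero, so proliferation-inducing drugs score
negative. Curves that dip below zero without ever clearing the threshold
score 0 — they show no measured benefit but no net proliferation either.
The integral is evaluated in closed form (the 4PL has an elementary
antiderivative; the single threshold and cap crossings of the monotone
curve are located analytically) with an adaptive-quadrature route
(`integrate`, absolute tolerance $10^{-8}$) kept as a cross-check; the two
agree to $10^{-6}$. The score depends only on the log-range and curve
shape, so it is invariant to the concentration unit.

Effectiveness classes: effective DSS > 10, moderately effective
0 < DSS ≤ 10, ineffective DSS ≤ 0. A score of exactly 0 — zero area above
threshold — is classed ineffective: a drug with no measured effect cannot
be "moderately effective", and waterfall plots conventionally show DSS = 0
as the ineffective (blank) state. Series that cannot be fit (after QC)
fall back to trapezoidal integration of the replicate-mean inhibition with
the same branch rules, flagged `fallback`, so every tested drug receives a
score.

## Recommendations and reports

A drug is actionable iff its absolute IC50 and library Cmax both exist and
IC50 ≤ Cmax. Drugs without a pharmacokinetic reference are never
auto-recommended; they are listed in the report annex for physician
review — a fail-safe default, since dosing judgment is out of scope.
Actionable drugs rank by DSS descending; ties break by the smaller
IC50/Cmax ratio (more clinical headroom first), then drug id, making
reports byte-stable across runs. Combinations are ranked like any other
tested series and annotated with the best constituent DSS and a
super-additivity flag. The clinically actionable window is 28 days
(≤ 28, whole-day accounting); the feasibility endpoint is the proportion
of enrolled patients reported within it, tested one-sided against a 30%
null with the exact binomial test and reported with the two-sided 95%
Clopper–Pearson interval.

## Outcome statistics

*PFS ratio.* Current over previous progression-free survival for the same
patient; ratio ≥ 1.3 counts as clinical benefit. Patients without a
previous PFS are *unevaluable*, not negative. Because registries often
assign such patients a floor instead, `cohort_comparison()` takes an
explicit `na_prev_pfs` policy — `"exclude"` (default) or a numeric floor
in weeks — rather than hard-coding either convention. Censored current
PFS enters the ratio as observed (conservative when an ongoing response
already exceeds 1.3× the previous PFS) and enters the logrank test through
its event flag.

*Barnard's unconditional test.* For a 2×2 table with independent binomial
columns, the statistic is the pooled-variance score
$Z = (\hat p_1 - \hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$, and
the p-value is the supremum over the nuisance success probability $\pi$ of
the null probability of the extreme region, maximized on a $10^{-4}$ grid
with golden-section refinement around the grid optimum (deterministic; the
region probability is a polynomial in $\pi$, grouped by total successes
for speed). Two-sided extremeness uses $|Z| \ge |Z_{obs}|$ with one
deliberate refinement: outcomes whose $|Z|$ ties $|Z_{obs}|$ *exactly* are
counted only on the observed statistic's side (`ties = "observed"`, the
default). Mirror tables (swap successes/failures in both groups) tie
exactly by symmetry, and prevailing implementations resolve that tie by
floating-point accident rather than by policy; making the observed-side
rule explicit reproduces their published values deterministically, and
`ties = "both"` is available for the fully symmetric region. No multiple
testing correction is applied anywhere — each test is reported as run.

*Exact paired Wilcoxon.* Two-sided P by enumeration of all $2^n$ sign
assignments for up to 20 non-zero differences (zeros dropped and
counted), normal approximation with continuity and tie correction beyond.

*Delegated tests.* Clopper–Pearson and the exact binomial test use
`stats::binom.test`'s conventions (two-sided binomial P by small-probability
summation); logrank uses `survival::survdiff`; Mann–Whitney,
Kruskal–Wallis and Spearman use `stats::wilcox.test`, `kruskal.test` and
`cor.test` (Spearman exact for tie-free n ≤ 10, t-approximation
otherwise).

*ROC cutoff.* AUC by pairwise concordance (ties ½). The optimal DSS
cutoff maximizes the Youden index over the observed scores under the rule
"predict responder when DSS > cutoff", ties resolving to the smallest
cutoff; accuracy, PPV, NPV, recall, MCC and F1 are evaluated there. With
small cohorts these metrics are highly discrete; AUC = 1 occurs exactly
when responder and non-responder scores separate.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the screen's *design*: duplicate 10-point series
(10 µM–0.5 nM), 16 DMSO and 16 benzethonium wells per 384-well plate,
multiplicative log-normal well noise (luminescence is positive and
heteroscedastic, so additive Gaussian noise would be wrong), negative
controls at 100,000 RLU (CV 5%), positives at 2,000 RLU (CV 10%) — typical
ATP-luminescence scales that clear the 5,000-RLU rescue threshold by
construction — and a 10% plate failure rate realized as collapsed control
separation with inflated variance. Drug wells map the patient's latent
4PL response through the inverse of the pipeline's normalization
($L = \mu_n - (\mu_n-\mu_p)\,y/100$, then noise), so at zero noise the
pipeline is exactly the identity on the generative model — the basis of
the end-to-end recovery tests.

Per-patient drug sensitivity is a three-class mixture — sensitive (15%,
EC50 ~ lognormal(0.05 µM), near-complete kill), moderately sensitive (11%,
EC50 ~ 0.8 µM, partial inhibition 25–55%), resistant (74%, negligible
inhibition) — calibrated once so that a 125-drug screen yields a median of
21 effective (DSS > 10) and 12 moderately effective drugs per patient, the
marginal behavior expected of a refractory-cancer screen of approved
agents. Clinical coupling is linear:
$PFS = 10 + 1.0 \cdot DSS_{admin} + \varepsilon$, $\varepsilon \sim
N(0, 8^2)$ weeks, with objective response when the latent benefit
$1.0 \cdot DSS_{admin} + \varepsilon'$ exceeds 25; guided patients receive
their top latent-DSS drug, comparator patients a random one. With those
scales the DSS–PFS rank correlation sits in the high-0.8s at n ≈ 14, the
regime the outcome statistics are exercised in.

What the generator does *not* emulate: spatial plate artifacts (edge
evaporation, dispenser drift), readout saturation, mixed tumor/stromal
cell populations and culture adaptation, inter-drug correlation within a
class (each drug draws independently), informative censoring, or
per-tumor-type outcome heterogeneity. Tests passing on synthetic cohorts
therefore validate the *computational* contract — normalization, fitting,
scoring, gating and the statistics — not the biological fidelity of any
particular screen.

## Numerical choices and degenerate inputs

- Z′ requires ≥ 2 wells per control group and distinct control means;
  equal means raise an undefined-separation error rather than returning
  ±Inf.
- Fit tolerances: `ftol = ptol = 1e-15` (bounded LM), which recovers
  noise-free parameters to ~10⁻¹² relative error; RSS ties use a 10⁻¹²
  band before the smaller-EC50 rule.
- DSS integration: closed form by default; quadrature tolerance 10⁻⁸;
  scores are clamped at 100 against last-ulp overshoot.
- Barnard: nuisance grid step 10⁻⁴ plus refinement; extremeness tie band
  10⁻⁹ on the score scale.
- Exact Wilcoxon switches to the corrected normal approximation above 20
  non-zero differences (2²⁰ sign vectors is the practical enumeration
  limit).
- Degenerate tables (no failures anywhere, all-zero differences,
  single-class ROC labels, constant Spearman vectors) return P = 1 or an
  explicit error, never NaN.

## Problem sizes used by the test-suite simulations

Property suites run at sizes chosen to make their Monte-Carlo bounds
sharp but cheap: 1,000 random curves for the closed-form/quadrature DSS
agreement, 100 noisy curves for EC50 recovery (median relative error
< 15% at 5% noise), 200 plates for the control-separation sampling
property, 10,000 binomial draws per probability for Clopper–Pearson
coverage, 1,000 outcome-only null cohorts for the Spearman type-I
calibration, and exhaustive oracle sweeps over every 2×2 outcome of the
6-vs-8 and 8-vs-8 group designs for Barnard's test.

## Known limitations

- The DSS contract here is a fixed, fully specified variant (area above
  t = 10 on the log10 domain, normalized by $(100-t)\Delta x$); numeric
  identity with other DSS software variants is not claimed.
- Curve fitting assumes a monotone single-site dose–response; biphasic or
  bell-shaped responses are fit by their best monotone approximation.
- Barnard's supremum is over a finite grid plus local refinement; p-values
  are accurate to well below the 10⁻⁴ grid step but are not closed-form.
- The Cox proportional-hazards analysis of paired survival (clustered
  variance) is out of scope; `cohort_comparison()` covers the exact,
  rank-based and logrank comparisons.
- Recommendation ranking encodes one defensible tie-break (DSS, then
  IC50/Cmax headroom); a tumor board weighing toxicity or availability
  will re-order within ties.
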