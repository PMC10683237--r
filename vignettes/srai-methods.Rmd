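---
title: "Methods: scoring and validating the sepsis renal angina index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating the sepsis renal angina index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srai)
```

## The clinical problem

Roughly one in five children with septic shock develops severe acute
kidney injury (AKI, KDIGO stage 2 or higher) by Day 3 of the PICU stay,
with sharply higher mortality and resource use. Only supportive kidney
protection is available once severe AKI is established, so the practical
question is early risk stratification: which children, on Day 1, warrant
conservative fluid management, nephrotoxin avoidance, biomarker testing or
transfer to a KRT-capable centre?

The renal angina index (RAI) answers this with a deliberately simple
product score. A **risk stratum** captures susceptibility — 1 for any ICU
admission, 3 for a history of solid-organ or stem-cell transplant, 5 for
concurrent invasive ventilation and vasoactive support — and an **injury
stratum** captures early injury signal — 1/2/4/8 from the Day-1 serum
creatinine ratio over baseline (tiers at >1, ≥1.5, ≥2) and the Day-1
percent fluid balance (tiers at ≥5%, ≥10%, ≥15%), each axis scored and the
higher tier kept. The score is the product, 1–40, and a score ≥ 8 fulfils
renal angina (RAI+).

In septic shock specifically, early creatinine elevation, large-volume
resuscitation and organ support are near-universal, which erodes the RAI's
specificity. The sepsis modification (sRAI) therefore demotes intermediate
scores by a marker of sepsis severity, thrombocytopenia:

* sRAI+ : RAI ≥ 20, **or** RAI in [8, 20) with platelets < 150 × 10³/µL;
* sRAI− : RAI < 8, **or** RAI in [8, 20) with platelets ≥ 150 × 10³/µL.

The modification can only demote, so the sRAI+ set is always a subset of
the RAI+ set — a structural invariant the test suite checks on every
generated cohort.

## Outcome definition and baseline creatinine

The primary outcome is Day-3 severe AKI: Day-3 serum creatinine at least
twice baseline (KDIGO stage ≥ 2 by creatinine criteria). Urine-output
criteria are out of scope, as reliable urine output is rarely available in
this setting; staging by creatinine alone may therefore undercall AKI.

Baseline creatinine resolution follows a strict priority:

1. **measured** — the lowest value in the three months before admission;
2. **height-based back-calculation** — when no measured value exists but
   height does, baseline = 0.413 × height(cm) / 120, i.e. the bedside
   height-based pediatric eGFR formula solved for creatinine at an assumed
   eGFR of 120 ml/min/1.73 m²;
3. **age-based (Pottel)** — with neither measurement nor height, baseline
   is the age-specific median creatinine Q(age) = 0.0270·age + 0.2329
   mg/dL (ages 1–14; sex-specific adolescent medians 0.90/0.70 mg/dL above
   14), scaled by 107.3/120 so the implied height-independent eGFR is also
   120. Ages below 1 year are outside the published range of the age
   formula and raise an error rather than extrapolate.

Both imputation constants (`egfr_target`, `schwartz_k`) are exposed as
arguments. Two boundary conventions are applied exactly as published and
are deliberately asymmetric: Day-1 elevation ("D1 SCr > Baseline +") is
the *strict* condition ratio > 1, while severe AKI is the *inclusive*
condition ratio ≥ 2. A patient on KRT on Day 3 with missing creatinine is
excluded under the default creatinine-only reading; setting
`krt_counts_as_severe = TRUE` instead applies the KDIGO stage-3-by-KRT
rule. We default to the creatinine-only letter of the outcome definition
and surface the alternative as configuration, because the two readings
change the denominator of every downstream metric.

## Diagnostic performance

All accuracy statistics flow through an explicit 2×2 table
(`contingency_table`, or `contingency_from_margins` when rebuilding tables
from published margins). Sensitivity, specificity, PPV and NPV carry
exact Clopper–Pearson intervals (beta-quantile tail inversion); likelihood
ratios carry log-method intervals with variance
1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn) (mirrored for the negative LR). The
choice of the exact interval is not cosmetic: it reproduces all eight
published interval bounds for the sRAI row after integer-percent rounding,
which a Wilson interval does not for the upper sensitivity bound.

Report rounding is: percentages to whole percents, half away from zero;
ratio-scale estimates (RR, OR, LR) to two significant figures with
trailing zeros dropped. All internal arithmetic is full precision; the 95%
normal quantile is fixed at 1.959964.

ROC analysis is fully nonparametric: the AUROC is the Mann–Whitney
statistic with half-credit for ties — stated explicitly because the RAI
takes only twelve distinct values, so ties are the norm, not the edge case
— and its variance and the paired two-classifier comparison use DeLong
placement values computed from midranks. Degenerate inputs (single-class
labels) raise; a zero-variance difference with zero AUC difference returns
p = 1 exactly. Because a published AUROC of a *binary* designation cannot
exceed (sens + spec)/2, the pipeline reports the ROC of the raw RAI score
and of the sRAI designation separately and asserts no parity between the
binary designation's AUROC and the published curve, whose underlying
continuous score is not recoverable from the printed tables.

## Association analyses

Group comparisons use Wilcoxon rank-sum for continuous variables and
chi-square without continuity correction for 2×2 tables, substituting
Fisher's exact test when any expected cell is below 5 — the combination
that reproduces the published mortality-by-sRAI p = 0.013. Relative risks
use the log-Wald interval. Covariates are screened bivariately at p < 0.15,
with sRAI-internal components (transplant history, vasoactives,
ventilation, fluid balance, platelets) excluded a priori for collinearity
with the exposure.

The multivariable logistic models regress Day-3 severe AKI and first-week
KRT on sRAI positivity, Day-1 creatinine elevation and the screened
covariates. Both models exclude patients already on KRT on Day 1, whose
Day-1 creatinine is uninterpretable under dialysis — we apply this
exclusion to both models, reading the analysis description as governing
all regressions. PERSEVERE-II enters multiplied by 10 so its odds ratio is
per 0.1 of mortality probability. Fits are maximum likelihood via IRLS
with a tightened convergence tolerance (deviance epsilon 1e−12), which
makes the single-binary-covariate odds ratio agree with the 2×2
cross-product ratio to ~1e−10 — an identity the tests assert. Complete
separation is reported as a structured diagnostic (`separation_suspected`,
`converged = FALSE`), never as silent coefficients.

## The synthetic cohort generator

The validation study's patient-level data are not deposited, so the
package ships a generator whose defaults emulate the published cohort: a
single latent severity factor Z ~ N(0,1) induces all cross-variable
correlation, with organ-support flags following severity-conditioned
Bernoulli draws (marginal prevalences: transplant 9%, vasoactives 74%,
ventilation 56%; known baseline 56%, independent), and positive skewed
quantities drawn on the log scale with severity loadings (platelets median
153 ×10³/µL, creatinine ratio median 1.3, fluid balance median 3.9% via a
shifted lognormal, VIS, PRISM III, PERSEVERE-II with its 0.007 floor).
Heights come from a smooth growth-curve approximation of age so the
height-based imputation path is exercised on the 44% of records with
baseline withheld.

Day-3 severe AKI follows a logistic link on the log creatinine ratio,
positive fluid balance, thrombocytopenia and Z; Day-3 creatinine is then
back-solved from the sampled AKI state so that staging the generated data
reproduces the generated outcome exactly. Two idealisations are worth
stating plainly. First, the generator anchors each patient's creatinine
trajectory to the baseline the pipeline will *resolve* (the measured value
when known, otherwise the height-based imputation), so imputation error
does not blur the outcome; real cohorts do not enjoy this, and passing
calibration tests therefore demonstrates the machinery, not robustness to
baseline misclassification. Second, a single latent factor is the simplest
structure that can reproduce the published marginals together with a
realistic score–outcome AUROC; it is a modelling choice, not a claim about
the study's joint distribution, and the published adjusted odds ratios and
AUROC are deliberately not point targets (they are unidentifiable from
printed summaries).

The outcome-link coefficients were calibrated once against the published
operating point — Day-3 severe AKI 22%, sRAI positivity 39%, sensitivity
85%, specificity 74% (tolerances about ±7 percentage points over seeds) —
and frozen as the shipped defaults; `calibrate_to_paper()` returns exactly
these. Per-variable substreams derive from the single seed, so changing
one block's parameters does not perturb another block's draws, and
generation is byte-deterministic given the seed.

Remaining open quantities were set once to field-plausible values: the
PRISM-III/PERSEVERE-II correlation arises implicitly through their shared
severity loadings (about 0.5 on the latent scale); KRT probability is 0.50
given AKI and 0.02 otherwise (marginal ≈ 13.5%), with 53% of recipients
already on KRT on Day 1; 28-day mortality is 19% with AKI and 4% without
(marginal ≈ 7.2%).

## Problem sizes and numerical checks in the test suite

The suite verifies the AUROC engine exhaustively against brute-force pair
counting for every labelling up to n = 8 and on 100 random tied instances
at n = 50; DeLong size is checked over 200 null replicates at n = 200
(empirical type-I error required in (0.01, 0.10) at α = 0.05); logistic
parameter recovery uses 50 replicates of n = 5000 with a true exposure OR
of 4.5, requiring the mean recovered OR within 15%; generator calibration
averages 20 cohorts of n = 5000. These sizes keep each property
comfortably identifiable while the whole suite runs in well under a
minute.

## Known limitations

* Creatinine-only AKI staging; no urine-output criteria.
* The generator's latent-factor structure cannot, and does not try to,
  reproduce adjusted (conditional) effect sizes from the study.
* The Pottel age path errors below 1 year rather than extrapolating; in
  practice that path is only reached by records lacking both a measured
  baseline and a height.
* The Day-1 scoring window is the first 24 h after meeting shock criteria
  (as validated for this population), not the original 12-h window.

## A worked end-to-end run

```{r example, eval = FALSE}
report <- run_validation(config = cohort_config(n = 800, seed = 31))
print(report)
write_report(report, "validation_report.json")

# the published tables, rebuilt from the packaged printed counts
fixture_report()$classifiers$srai$formatted
```
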