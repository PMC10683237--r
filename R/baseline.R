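# Baseline serum creatinine resolution, Day-1 injury markers, KDIGO Day-3
# staging and PICU-free days.
#
# Baseline SCr priority: (1) lowest measured value in the prior 3 months,
# (2) back-calculation from the bedside height-based pediatric eGFR formula
# (k * height / SCr) at a target eGFR of 120 ml/min/1.73m^2, (3) the
# age-based Pottel method using the age-specific median creatinine Q(age),
# scaled so the implied height-independent eGFR (107.3 / (SCr/Q)) is 120.

POTTEL_EGFR_CONST <- 107.3  # height-independent eGFR numerator, ml/min/1.73m^2

#' Age-specific median serum creatinine Q(age)
#'
#' The Pottel height-independent framework's normal median creatinine for
#' children: Q(age) = 0.0270 * age + 0.2329 mg/dL for ages 1-14 years.
#' Above 14 years the adolescent/adult full-age-spectrum medians are used
#' (0.90 mg/dL male, 0.70 mg/dL female). Ages below 1 year are outside the
#' published range and raise an error.
#'
#' @param age Age in years (vector).
#' @param male Logical vector, required for ages above 14.
#' @return Median creatinine in mg/dL.
#' @export
pottel_q <- function(age, male = NA) {
  if (any(is.na(age) | age < 1))
    abort("pottel_q: age missing or below the published range (>= 1 year)")
  male <- rep_len(male, length(age))
  adult <- age > 14
  if (any(adult & is.na(male)))
    abort("pottel_q: sex required for ages above 14 years")
  q <- 0.0270 * age + 0.2329
  q[adult] <- ifelse(male[adult], 0.90, 0.70)
  q
}

#' Resolve baseline serum creatinine
#'
#' Priority order: measured lowest value in the prior three months; else
#' back-calculation from the height-based bedside eGFR formula at a target
#' eGFR (SCr = k * height / eGFR); else the age-based Pottel median
#' creatinine scaled to the same target eGFR.
#'
#' @param baseline_scr_known Measured baseline SCr (mg/dL) or `NA`.
#' @param height_cm Height in cm or `NA`.
#' @param age Age in years.
#' @param male Logical (needed only for the Pottel path above age 14).
#' @param egfr_target Target eGFR for imputation, default 120 ml/min/1.73m^2.
#' @param schwartz_k Bedside height-based formula constant, default 0.413.
#' @return A data frame with `baseline_scr` (mg/dL) and `baseline_source`
#'   (`"measured"`, `"egfr120_height"` or `"pottel_age"`).
#' @export
resolve_baseline_scr <- function(baseline_scr_known, height_cm, age, male = NA,
                                 egfr_target = 120, schwartz_k = 0.413) {
  n <- max(length(baseline_scr_known), length(height_cm), length(age))
  known <- rep_len(baseline_scr_known, n)
  h <- rep_len(height_cm, n)
  age <- rep_len(age, n)
  male <- rep_len(male, n)

  src <- ifelse(!is.na(known), "measured",
                ifelse(!is.na(h), "egfr120_height", "pottel_age"))
  out <- numeric(n)
  out[src == "measured"] <- known[src == "measured"]
  out[src == "egfr120_height"] <-
    schwartz_k * h[src == "egfr120_height"] / egfr_target
  pot <- src == "pottel_age"
  if (any(pot)) {
    if (any(is.na(age[pot]) | age[pot] <= 0))
      abort("resolve_baseline_scr: no measured baseline, no height, and age ",
            "missing or non-positive; baseline unresolvable")
    out[pot] <- pottel_q(age[pot], male[pot]) *
      POTTEL_EGFR_CONST / egfr_target
  }
  if (any(out <= 0))
    abort("resolve_baseline_scr: resolved a non-positive baseline")
  data.frame(baseline_scr = out,
             baseline_source = factor(src, levels = c("measured",
                                                      "egfr120_height",
                                                      "pottel_age")))
}

#' Day-1 creatinine ratio over baseline
#'
#' @param d1_scr Day-1 serum creatinine (mg/dL).
#' @param baseline_scr Resolved baseline creatinine (mg/dL).
#' @return The dimensionless ratio. Day-1 elevation above baseline
#'   ("D1 SCr > Baseline +") is the strict condition `ratio > 1`.
#' @export
scr_ratio <- function(d1_scr, baseline_scr) {
  if (any(is.na(d1_scr) | d1_scr <= 0) || any(is.na(baseline_scr) | baseline_scr <= 0))
    abort("scr_ratio: creatinine values must be present and > 0")
  d1_scr / baseline_scr
}

#' Day-1 percent fluid balance
#'
#' %FB = (fluid in - fluid out) / admission weight x 100. Negative values
#' indicate net fluid loss.
#'
#' @param in_L,out_L Day-1 fluid totals in liters (>= 0).
#' @param weight_kg Admission weight in kg (> 0).
#' @return Signed percent of body weight.
#' @export
fluid_balance_percent <- function(in_L, out_L, weight_kg) {
  if (any(is.na(weight_kg) | weight_kg <= 0))
    abort("fluid_balance_percent: weight must be > 0")
  if (any(is.na(in_L) | in_L < 0) || any(is.na(out_L) | out_L < 0))
    abort("fluid_balance_percent: fluid volumes must be present and >= 0")
  (in_L - out_L) / weight_kg * 100
}

#' Stage Day-3 severe acute kidney injury
#'
#' KDIGO stage 2 or higher by creatinine criteria: Day-3 SCr at least twice
#' baseline. Optionally, receipt of kidney replacement therapy on Day 3
#' counts as severe AKI (the KDIGO stage-3 criterion); the default is the
#' creatinine-only reading.
#'
#' @param d3_scr Day-3 serum creatinine (mg/dL); may be `NA` only when
#'   `d3_krt` is `TRUE` and `krt_counts_as_severe` is enabled.
#' @param baseline_scr Resolved baseline creatinine (> 0).
#' @param d3_krt Logical, KRT on Day 3.
#' @param krt_counts_as_severe If `TRUE`, Day-3 KRT implies severe AKI
#'   regardless of creatinine. Default `FALSE`.
#' @return Logical vector.
#' @export
stage_d3_severe_aki <- function(d3_scr, baseline_scr, d3_krt = FALSE,
                                krt_counts_as_severe = FALSE) {
  n <- max(length(d3_scr), length(baseline_scr), length(d3_krt))
  d3_scr <- rep_len(d3_scr, n)
  baseline_scr <- rep_len(baseline_scr, n)
  d3_krt <- rep_len(d3_krt, n)
  if (any(is.na(baseline_scr) | baseline_scr <= 0))
    abort("stage_d3_severe_aki: baseline must be present and > 0")
  by_krt <- krt_counts_as_severe & !is.na(d3_krt) & d3_krt
  need_scr <- !by_krt
  if (any(need_scr & is.na(d3_scr)))
    abort("stage_d3_severe_aki: Day-3 SCr missing and KRT rule not applicable")
  out <- by_krt
  out[need_scr] <- d3_scr[need_scr] / baseline_scr[need_scr] >= 2.0
  out
}

#' PICU-free days to day 28
#'
#' 28 minus the PICU length of stay, floored at zero; patients who died in
#' the PICU within 28 days are assigned 0.
#'
#' @param los_days PICU length of stay in days (>= 0).
#' @param died_in_picu_by_28 Logical.
#' @return Days, in \[0, 28\].
#' @export
picu_free_days <- function(los_days, died_in_picu_by_28) {
  if (any(is.na(los_days) | los_days < 0))
    abort("picu_free_days: length of stay must be present and >= 0")
  ifelse(died_in_picu_by_28, 0, pmax(28 - los_days, 0))
}

#' Resolve per-patient renal status
#'
#' Runs baseline resolution, Day-1 injury markers and Day-3 staging over a
#' cohort.
#'
#' @param cohort A validated cohort (after exclusions, so Day-1 and Day-3
#'   creatinine are present).
#' @param egfr_target,schwartz_k Passed to [resolve_baseline_scr()].
#' @param krt_counts_as_severe Passed to [stage_d3_severe_aki()].
#' @return A data frame keyed by `patient_id` with `baseline_scr`,
#'   `baseline_source`, `d1_scr_ratio`, `d1_scr_above_baseline`,
#'   `fb_percent`, `d3_severe_aki` and `picu_free_days`.
#' @export
renal_status <- function(cohort, egfr_target = 120, schwartz_k = 0.413,
                         krt_counts_as_severe = FALSE) {
  base <- resolve_baseline_scr(cohort$baseline_scr_known, cohort$height_cm,
                               cohort$age, cohort$male,
                               egfr_target = egfr_target,
                               schwartz_k = schwartz_k)
  ratio <- scr_ratio(cohort$d1_scr, base$baseline_scr)
  fb <- fluid_balance_percent(cohort$d1_fluid_in_L, cohort$d1_fluid_out_L,
                              cohort$weight_kg)
  aki <- stage_d3_severe_aki(cohort$d3_scr, base$baseline_scr, cohort$d3_krt,
                             krt_counts_as_severe = krt_counts_as_severe)
  data.frame(patient_id = cohort$patient_id,
             baseline_scr = base$baseline_scr,
             baseline_source = base$baseline_source,
             d1_scr_ratio = ratio,
             d1_scr_above_baseline = ratio > 1,
             fb_percent = fb,
             d3_severe_aki = aki,
             picu_free_days = picu_free_days(cohort$picu_los_days,
                                             cohort$died_by_day28),
             stringsAsFactors = FALSE)
}
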