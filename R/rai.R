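# The renal angina index and its sepsis modification.
#
# The RAI is the product of a risk stratum (1/3/5: ICU admission /
# transplant history / ventilation plus vasoactives) and an injury stratum
# (1/2/4/8 from Day-1 creatinine elevation over baseline and percent fluid
# balance), giving a score between 1 and 40; a score >= 8 fulfils renal
# angina (RAI+). The sepsis modification reclassifies intermediate scores
# by Day-1 platelet count: sRAI+ is RAI >= 20, or RAI in [8, 20) with
# platelets < 150 x 10^3/uL.

RISK_TIERS <- c(1L, 3L, 5L)
INJURY_TIERS <- c(1L, 2L, 4L, 8L)

#' Default injury-stratum boundaries
#'
#' Cut points for the injury axis of the RAI. The creatinine-ratio tiers
#' are 1 (no elevation), 2 (ratio above 1 but below 1.5), 4 (1.5 to below
#' 2) and 8 (at least 2, the severe-AKI-equivalent stratum); the fluid-
#' balance tiers are 1 (< 5%), 2 (>= 5%), 4 (>= 10%) and 8 (>= 15%). The
#' patient's injury stratum is the higher of the two.
#'
#' @return A list with numeric vectors `ratio` and `fb` of ascending cut
#'   points for tiers 2, 4 and 8.
#' @export
rai_injury_breaks <- function() {
  list(ratio = c(1, 1.5, 2), fb = c(5, 10, 15))
}

#' Risk stratum of the renal angina index
#'
#' Highest applicable tier: every patient in this setting is an ICU
#' admission (tier 1); a history of solid-organ or stem-cell transplant is
#' tier 3; concurrent invasive mechanical ventilation and vasoactive
#' support is tier 5.
#'
#' @param transplant_history,d1_mech_vent,d1_vasoactive Logical vectors.
#' @return Integer tier in \{1, 3, 5\}.
#' @export
risk_stratum <- function(transplant_history, d1_mech_vent, d1_vasoactive) {
  n <- max(length(transplant_history), length(d1_mech_vent),
           length(d1_vasoactive))
  transplant_history <- rep_len(transplant_history, n)
  both <- rep_len(d1_mech_vent, n) & rep_len(d1_vasoactive, n)
  ifelse(both, 5L, ifelse(transplant_history, 3L, 1L))
}

#' Injury stratum of the renal angina index
#'
#' Maximum of the creatinine-ratio tier and the fluid-balance tier under
#' the boundaries of [rai_injury_breaks()]. A missing fluid balance is
#' scored from the creatinine ratio alone (tier-1 fluid evidence) with a
#' warning, mirroring bedside practice of scoring available criteria.
#'
#' @param scr_ratio Day-1 creatinine over baseline (> 0).
#' @param fb_percent Day-1 percent fluid balance; may be `NA`.
#' @param breaks Boundary list, see [rai_injury_breaks()].
#' @return Integer tier in \{1, 2, 4, 8\}.
#' @export
injury_stratum <- function(scr_ratio, fb_percent,
                           breaks = rai_injury_breaks()) {
  if (any(is.na(scr_ratio) | scr_ratio <= 0))
    abort("injury_stratum: scr_ratio must be present and > 0")
  n <- max(length(scr_ratio), length(fb_percent))
  scr_ratio <- rep_len(scr_ratio, n)
  fb_percent <- rep_len(fb_percent, n)
  tier_of <- function(x, cuts, first_strict) {
    # tier index by ascending cut points; the ratio axis is strict at its
    # first cut (elevation means strictly above baseline) but inclusive at
    # 1.5x and 2x, matching the printed strata
    idx <- findInterval(x, cuts)
    if (first_strict) idx[x == cuts[1]] <- 0L
    INJURY_TIERS[idx + 1L]
  }
  rt <- tier_of(scr_ratio, breaks$ratio, first_strict = TRUE)
  if (any(is.na(fb_percent))) {
    warning(sum(is.na(fb_percent)),
            " record(s) missing fluid balance; injury tier scored from ",
            "creatinine ratio alone", call. = FALSE)
  }
  ft <- ifelse(is.na(fb_percent), 1L,
               tier_of(fb_percent, breaks$fb, first_strict = FALSE))
  pmax(rt, ft)
}

#' Compute the renal angina index score
#'
#' @param risk_tier Integer in \{1, 3, 5\}.
#' @param injury_tier Integer in \{1, 2, 4, 8\}.
#' @return A data frame with `rai_score` (product, in 1..40) and
#'   `rai_positive` (score >= 8, renal angina fulfilment).
#' @export
compute_rai <- function(risk_tier, injury_tier) {
  if (!all(risk_tier %in% RISK_TIERS))
    abort("compute_rai: risk tier must be one of ",
          paste(RISK_TIERS, collapse = ", "))
  if (!all(injury_tier %in% INJURY_TIERS))
    abort("compute_rai: injury tier must be one of ",
          paste(INJURY_TIERS, collapse = ", "))
  score <- as.integer(risk_tier * injury_tier)
  data.frame(rai_score = score, rai_positive = score >= 8L)
}

#' Sepsis renal angina classification (sRAI)
#'
#' Positive when the RAI score is at least 20, or between 8 and below 20
#' with a Day-1 platelet count under 150 x 10^3/uL; negative otherwise.
#' Platelets are required only in the intermediate band.
#'
#' @param rai_score Integer RAI score (1..40).
#' @param d1_platelets Day-1 platelet count, 10^3 cells/uL.
#' @return Logical vector, sepsis renal angina fulfilment.
#' @export
classify_srai <- function(rai_score, d1_platelets) {
  n <- max(length(rai_score), length(d1_platelets))
  rai_score <- rep_len(rai_score, n)
  d1_platelets <- rep_len(d1_platelets, n)
  mid <- rai_score >= 8 & rai_score < 20
  if (any(mid & is.na(d1_platelets)))
    abort("classify_srai: platelet count required for RAI in [8, 20)")
  rai_score >= 20 | (mid & d1_platelets < 150)
}

#' Score a cohort on the RAI and sRAI
#'
#' Convenience wrapper producing per-patient tiers, score and
#' classifications from a cohort and its resolved renal status.
#'
#' @param cohort A validated cohort (post-exclusion).
#' @param status Output of [renal_status()] for the same rows; computed if
#'   `NULL`.
#' @param breaks Injury boundaries, see [rai_injury_breaks()].
#' @return A data frame with `patient_id`, `risk_tier`, `injury_tier`,
#'   `rai_score`, `rai_positive`, `srai_positive` and
#'   `d1_scr_above_baseline`.
#' @export
score_cohort <- function(cohort, status = NULL, breaks = rai_injury_breaks()) {
  if (is.null(status)) status <- renal_status(cohort)
  risk <- risk_stratum(cohort$transplant_history, cohort$d1_mech_vent,
                       cohort$d1_vasoactive)
  injury <- injury_stratum(status$d1_scr_ratio, status$fb_percent, breaks)
  rai <- compute_rai(risk, injury)
  data.frame(patient_id = cohort$patient_id,
             risk_tier = risk,
             injury_tier = injury,
             rai_score = rai$rai_score,
             rai_positive = rai$rai_positive,
             srai_positive = classify_srai(rai$rai_score, cohort$d1_platelets),
             d1_scr_above_baseline = status$d1_scr_above_baseline,
             stringsAsFactors = FALSE)
}
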