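# A minimal valid patient record with overridable fields, and a tiny
# handmade cohort builder used across the suite.

make_patient <- function(...) {
  rec <- list(
    patient_id = "P1", age = 10, male = TRUE, transplant_history = FALSE,
    height_cm = 138, weight_kg = 32, baseline_scr_known = 0.36,
    d1_scr = 0.40, d3_scr = 0.45, d1_platelets = 200,
    d1_fluid_in_L = 2.0, d1_fluid_out_L = 1.5, d1_mech_vent = FALSE,
    d1_vasoactive = TRUE, d1_vis = 5, prism_iii = 8L, persevere_ii = 0.05,
    krt_day1 = FALSE, krt_day1_7 = FALSE, d3_krt = FALSE,
    picu_los_days = 4, died_by_day28 = FALSE, esrd_or_unknown_ckd = FALSE)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  if (!length(rows)) rows <- list(make_patient())
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    r$patient_id <- paste0("P", i)
    r
  }))
  rownames(out) <- NULL
  out
}

# a small generated-but-fixed analysis-ready cohort for integration tests
small_cohort <- function(n = 400, seed = 42) {
  suppressWarnings(generate_cohort(cohort_config(n = n, seed = seed)))
}
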