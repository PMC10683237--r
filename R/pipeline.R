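# End-to-end orchestration: cohort -> exclusions -> renal status -> RAI/
# sRAI scoring -> diagnostic performance -> relative risks -> covariate
# screen -> multivariable models -> structured report.

classifier_block <- function(predicted, truth, ci_level = 0.95) {
  tab <- contingency_from_labels(predicted, truth)
  met <- diagnostic_metrics(tab, ci_level)
  rr <- relative_risk_from_table(tab, ci_level)
  pct <- met$metric %in% c("sensitivity", "specificity", "ppv", "npv")
  list(
    table = tab[c("tp", "fp", "fn", "tn")],
    n_positive = tab$tp + tab$fp,
    metrics = met,
    formatted = data.frame(
      metric = met$metric,
      estimate = ifelse(pct, fmt_pct(met$estimate), fmt_ratio(met$estimate)),
      ci = ifelse(pct, fmt_ci(met$ci_low, met$ci_high, "pct"),
                  fmt_ci(met$ci_low, met$ci_high, "ratio")),
      stringsAsFactors = FALSE),
    rr_outcome = rr[c("rr", "ci_low", "ci_high", "p_value")]
  )
}

rr_block <- function(events1, n1, events0, n0, ci_level = 0.95) {
  rr <- relative_risk(events1, n1, events0, n0, ci_level)
  list(events_exposed = events1, n_exposed = n1,
       events_ref = events0, n_ref = n0,
       rr = rr$rr, ci_low = rr$ci_low, ci_high = rr$ci_high,
       p_value = rr$p_value,
       formatted = sprintf("RR %s (%s)", fmt_ratio(rr$rr),
                           fmt_ci(rr$ci_low, rr$ci_high, "ratio")))
}

#' Run the full external-validation analysis
#'
#' Executes the complete pipeline on a supplied cohort or on a synthetic
#' cohort generated from `config`: validation, study exclusions, baseline
#' resolution and Day-3 KDIGO staging, RAI/sRAI scoring, per-classifier
#' diagnostic performance (sRAI, original RAI, Day-1 creatinine
#' elevation), ROC analysis with the paired DeLong comparison, relative
#' risks for kidney and mortality outcomes, bivariate covariate screening
#' and the two multivariable logistic models (Day-3 severe AKI; KRT in the
#' first week, both excluding Day-1 KRT patients).
#'
#' A degenerate cohort (no or only AKI events) yields a report with
#' `status = "degenerate"`, metrics marked undefined and the regression
#' stage skipped with a reason, rather than an error.
#'
#' @param cohort A cohort data frame (see [cohort_schema()]), or `NULL` to
#'   simulate.
#' @param config An [cohort_config()] used when `cohort` is `NULL`.
#' @param krt_counts_as_severe Day-3 staging rule, see
#'   [stage_d3_severe_aki()].
#' @param screen_alpha Bivariate screening threshold, default 0.15.
#' @param exclude_day1_krt Exclude Day-1 KRT patients from both regression
#'   models (the published reading of the Methods), default `TRUE`.
#' @param ci_level Confidence level for all intervals.
#' @return A list of class `srai_report`.
#' @export
run_validation <- function(cohort = NULL, config = NULL,
                           krt_counts_as_severe = FALSE,
                           screen_alpha = 0.15, exclude_day1_krt = TRUE,
                           ci_level = 0.95) {
  if (is.null(cohort)) {
    if (is.null(config)) config <- cohort_config()
    cohort <- generate_cohort(config)
  }
  cohort <- validate_cohort(cohort, strict = TRUE)
  ex <- apply_exclusions(cohort)
  d <- ex$included
  status <- renal_status(d, krt_counts_as_severe = krt_counts_as_severe)
  scores <- score_cohort(d, status)
  analysis <- cbind(d, status[, setdiff(names(status), "patient_id")],
                    scores[, setdiff(names(scores),
                                     c("patient_id", "d1_scr_above_baseline"))])
  analysis$d1_scr_above_baseline <- status$d1_scr_above_baseline

  aki <- status$d3_severe_aki
  report <- list(
    provenance = list(package = "srai",
                      version = as.character(utils::packageVersion("srai")),
                      seed = if (!is.null(config)) config$seed else NA,
                      n_input = ex$counts$n_input,
                      config = if (!is.null(config))
                        unclass(config) else NULL),
    exclusions = ex$counts,
    cohort_summary = list(
      n = nrow(d),
      n_d3_severe_aki = sum(aki),
      aki_rate = mean(aki),
      n_srai_positive = sum(scores$srai_positive),
      srai_positivity = mean(scores$srai_positive),
      n_rai_positive = sum(scores$rai_positive),
      n_d1scr_positive = sum(status$d1_scr_above_baseline),
      n_krt_day1_7 = sum(d$krt_day1_7),
      n_died = sum(d$died_by_day28))
  )

  degenerate <- !any(aki) || all(aki)
  if (degenerate) {
    report$status <- "degenerate"
    report$degenerate_reason <-
      if (!any(aki)) "no Day-3 severe AKI events" else
        "every patient has Day-3 severe AKI"
    report$classifiers <- NULL
    report$models <- list(skipped = TRUE,
                          reason = report$degenerate_reason)
    class(report) <- "srai_report"
    return(report)
  }
  report$status <- "complete"

  report$group_table_by_srai <- compare_groups(
    analysis, "srai_positive",
    variables = c("age", "male", "transplant_history", "prism_iii",
                  "persevere_ii", "baseline_scr", "d1_vis", "d1_mech_vent",
                  "d1_vasoactive", "fb_percent", "d1_scr_ratio",
                  "d1_platelets", "d3_severe_aki", "krt_day1_7",
                  "picu_free_days", "died_by_day28"))

  report$classifiers <- list(
    srai = classifier_block(scores$srai_positive, aki, ci_level),
    rai = classifier_block(scores$rai_positive, aki, ci_level),
    d1scr = classifier_block(status$d1_scr_above_baseline, aki, ci_level))

  roc_rai <- empirical_auroc(scores$rai_score, aki, ci_level)
  roc_srai <- empirical_auroc(as.numeric(scores$srai_positive), aki, ci_level)
  roc_ratio <- empirical_auroc(status$d1_scr_ratio, aki, ci_level)
  report$roc <- list(
    rai_score = roc_rai, srai_designation = roc_srai,
    d1_scr_ratio = roc_ratio,
    delong_rai_vs_ratio = delong_paired_test(scores$rai_score,
                                             status$d1_scr_ratio, aki),
    delong_srai_vs_ratio = delong_paired_test(as.numeric(scores$srai_positive),
                                              status$d1_scr_ratio, aki))

  srai_pos <- scores$srai_positive
  report$relative_risks <- list(
    d3_aki_by_srai = rr_block(sum(aki & srai_pos), sum(srai_pos),
                              sum(aki & !srai_pos), sum(!srai_pos), ci_level),
    krt_by_srai = rr_block(sum(d$krt_day1_7 & srai_pos), sum(srai_pos),
                           sum(d$krt_day1_7 & !srai_pos), sum(!srai_pos),
                           ci_level),
    mortality_by_srai = rr_block(sum(d$died_by_day28 & srai_pos),
                                 sum(srai_pos),
                                 sum(d$died_by_day28 & !srai_pos),
                                 sum(!srai_pos), ci_level),
    d3_aki_srai_vs_d1scr = rr_block(
      sum(aki & srai_pos), sum(srai_pos),
      sum(aki & status$d1_scr_above_baseline),
      sum(status$d1_scr_above_baseline), ci_level),
    mortality_by_aki = rr_block(sum(d$died_by_day28 & aki), sum(aki),
                                sum(d$died_by_day28 & !aki), sum(!aki),
                                ci_level))

  selected <- bivariate_screen(analysis, alpha = screen_alpha)
  report$screen <- list(selected = as.character(selected),
                        table = attr(selected, "screen"))

  fit_or_reason <- function(outcome) {
    y <- analysis[[outcome]]
    if (length(unique(y)) < 2)
      return(list(skipped = TRUE,
                  reason = paste0(outcome, " has a single class")))
    fit <- fit_logistic(analysis, outcome,
                        covariates = c(as.character(selected),
                                       "srai_positive",
                                       "d1_scr_above_baseline"),
                        exclude_day1_krt = exclude_day1_krt)
    fit[c("table", "n_used", "converged", "separation_suspected",
          "log_likelihood")]
  }
  report$models <- list(d3_severe_aki = fit_or_reason("d3_severe_aki"),
                        krt_day1_7 = fit_or_reason("krt_day1_7"))
  class(report) <- "srai_report"
  report
}

#' Reproduce the published performance tables from the printed counts
#'
#' Rebuilds every 2x2 table from the packaged published margins and
#' recomputes the full diagnostic-performance and relative-risk surface,
#' with report-rounded strings alongside full-precision estimates.
#'
#' @param fixture Output of [load_printed_fixture()].
#' @param ci_level Confidence level, default 0.95.
#' @return A list with per-classifier metric blocks and relative risks.
#' @export
fixture_report <- function(fixture = load_printed_fixture(),
                           ci_level = 0.95) {
  cls <- lapply(fixture$classifiers, function(cl) {
    tab <- contingency_from_margins(fixture$n_total, fixture$n_d3_aki,
                                    cl$n_positive, cl$n_true_positive)
    met <- diagnostic_metrics(tab, ci_level)
    pct <- met$metric %in% c("sensitivity", "specificity", "ppv", "npv")
    list(table = tab[c("tp", "fp", "fn", "tn")],
         metrics = met,
         formatted = data.frame(
           metric = met$metric,
           estimate = ifelse(pct, fmt_pct(met$estimate),
                             fmt_ratio(met$estimate)),
           ci = ifelse(pct, fmt_ci(met$ci_low, met$ci_high, "pct"),
                       fmt_ci(met$ci_low, met$ci_high, "ratio")),
           stringsAsFactors = FALSE))
  })
  fx <- fixture
  n_srai_pos <- fx$classifiers$srai$n_positive
  n_srai_neg <- fx$n_total - n_srai_pos
  srai_tab <- contingency_from_margins(fx$n_total, fx$n_d3_aki,
                                       n_srai_pos,
                                       fx$classifiers$srai$n_true_positive)
  rrs <- list(
    d3_aki_by_srai = rr_block(srai_tab$tp, n_srai_pos, srai_tab$fn,
                              n_srai_neg, ci_level),
    krt_by_srai = rr_block(fx$outcomes$krt_by_srai$events_positive,
                           n_srai_pos,
                           fx$outcomes$krt_by_srai$events_negative,
                           n_srai_neg, ci_level),
    mortality_by_srai = rr_block(fx$outcomes$mortality_by_srai$events_positive,
                                 n_srai_pos,
                                 fx$outcomes$mortality_by_srai$events_negative,
                                 n_srai_neg, ci_level),
    d3_aki_srai_vs_d1scr = rr_block(fx$classifiers$srai$n_true_positive,
                                    fx$classifiers$srai$n_positive,
                                    fx$classifiers$d1scr$n_true_positive,
                                    fx$classifiers$d1scr$n_positive,
                                    ci_level),
    mortality_by_aki = rr_block(fx$outcomes$mortality_by_aki$events_aki,
                                fx$n_d3_aki,
                                fx$outcomes$mortality_by_aki$events_no_aki,
                                fx$n_total - fx$n_d3_aki, ci_level))
  list(n_total = fx$n_total, n_d3_aki = fx$n_d3_aki,
       classifiers = cls, relative_risks = rrs)
}

#' Serialize a report to deterministic JSON
#'
#' Fixed key order, fixed precision and no timestamps, so identical inputs
#' produce byte-identical files.
#'
#' @param report A list (e.g. from [run_validation()] or
#'   [fixture_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(10),
                           na = "null", null = "null", dataframe = "columns")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.srai_report <- function(x, ...) {
  cat("sRAI validation report (status:", x$status, ")\n")
  cs <- x$cohort_summary
  cat(sprintf("  n = %d; D3 severe AKI %d (%s%%); sRAI+ %d (%s%%)\n",
              cs$n, cs$n_d3_severe_aki, fmt_pct(cs$aki_rate),
              cs$n_srai_positive, fmt_pct(cs$srai_positivity)))
  if (!is.null(x$classifiers)) {
    for (nm in names(x$classifiers)) {
      f <- x$classifiers[[nm]]$formatted
      cat(sprintf("  %-5s sens %s (%s) spec %s (%s) ppv %s npv %s +LR %s\n",
                  nm, f$estimate[1], f$ci[1], f$estimate[2], f$ci[2],
                  f$estimate[3], f$estimate[4], f$estimate[5]))
    }
  }
  invisible(x)
}
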