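# Association analyses: relative risks, two-group comparison tables,
# bivariate covariate screening, and multivariable logistic models.

#' Relative risk of an outcome between two groups
#'
#' Risk ratio with the log-Wald confidence interval
#' exp(ln RR +/- z * sqrt(1/a - 1/n1 + 1/c - 1/n0)) and a two-sided Wald
#' p-value on the log scale. Zero events in the reference arm yield an
#' infinite estimate with an undefined interval, flagged rather than
#' raised.
#'
#' @param events_exposed,n_exposed Events and size of the exposed group.
#' @param events_ref,n_ref Events and size of the reference group.
#' @param ci_level Confidence level, default 0.95.
#' @return A list with `rr`, `ci_low`, `ci_high`, `p_value`,
#'   `risk_exposed`, `risk_ref` and `undefined_ci` flag.
#' @export
relative_risk <- function(events_exposed, n_exposed, events_ref, n_ref,
                          ci_level = 0.95) {
  stopifnot(n_exposed > 0, n_ref > 0,
            events_exposed >= 0, events_exposed <= n_exposed,
            events_ref >= 0, events_ref <= n_ref)
  r1 <- events_exposed / n_exposed
  r0 <- events_ref / n_ref
  if (events_ref == 0) {
    return(list(rr = Inf, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, risk_exposed = r1, risk_ref = r0,
                undefined_ci = TRUE))
  }
  rr <- r1 / r0
  if (events_exposed == 0) {
    return(list(rr = 0, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, risk_exposed = r1, risk_ref = r0,
                undefined_ci = TRUE))
  }
  v <- 1 / events_exposed - 1 / n_exposed + 1 / events_ref - 1 / n_ref
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- exp(log(rr) + c(-1, 1) * z * sqrt(v))
  p <- 2 * stats::pnorm(-abs(log(rr) / sqrt(v)))
  list(rr = rr, ci_low = ci[1], ci_high = ci[2], p_value = p,
       risk_exposed = r1, risk_ref = r0, undefined_ci = FALSE)
}

#' Relative risk from a 2x2 contingency table
#'
#' Exposure is classifier positivity: compares event risk among test-
#' positives (`tp / (tp + fp)`) with test-negatives (`fn / (fn + tn)`).
#'
#' @param table An `srai_contingency` table.
#' @param ci_level Confidence level.
#' @return See [relative_risk()].
#' @export
relative_risk_from_table <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "srai_contingency"))
  relative_risk(table$tp, table$tp + table$fp,
                table$fn, table$fn + table$tn, ci_level = ci_level)
}

# two-sample test for one variable; chi-square without continuity
# correction for 2x2 unless an expected cell is below 5, then Fisher
two_group_p <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  if (length(unique(x)) < 2) return(list(p = NA_real_, test = "constant"))
  if (is.logical(x) || length(unique(x)) == 2) {
    tab <- table(factor(g, levels = c(FALSE, TRUE)), factor(x))
    if (any(dim(tab) < 2)) return(list(p = NA_real_, test = "constant"))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      list(p = stats::fisher.test(tab)$p.value, test = "fisher")
    } else {
      list(p = stats::chisq.test(tab, correct = FALSE)$p.value,
           test = "chisq")
    }
  } else {
    list(p = stats::wilcox.test(x ~ g, exact = FALSE)$p.value,
         test = "wilcoxon")
  }
}

#' Two-group comparison table
#'
#' Medians with interquartile ranges for continuous variables and n (%)
#' for binary variables, by a two-level grouping flag, with Wilcoxon
#' rank-sum, chi-square (no continuity correction) or Fisher's exact
#' p-values as appropriate (Fisher when any expected cell is below 5).
#'
#' @param data A data frame.
#' @param group Name of a logical grouping column.
#' @param variables Character vector of columns to compare; default all
#'   numeric/logical columns except the grouping flag.
#' @return A data frame with one row per variable: type, per-group summary
#'   (median \[IQR\] or n (%)), test used and p-value.
#' @export
compare_groups <- function(data, group, variables = NULL) {
  g <- data[[group]]
  if (is.null(g) || !is.logical(g)) abort("compare_groups: `group` must name a logical column")
  if (length(unique(g[!is.na(g)])) < 2)
    abort("compare_groups: grouping must have two non-empty levels")
  if (is.null(variables)) {
    variables <- setdiff(names(data)[vapply(data, function(v)
      is.numeric(v) || is.logical(v), logical(1))], group)
  }
  summ <- function(x, sel) {
    x <- x[sel & !is.na(x)]
    if (is.logical(x)) {
      sprintf("%d (%s%%)", sum(x), fmt_pct(mean(x)))
    } else {
      q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
      sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
    }
  }
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    tst <- two_group_p(x, g)
    data.frame(variable = v,
               type = if (is.logical(x)) "binary" else "continuous",
               group_false = summ(x, !g), group_true = summ(x, g),
               test = tst$test, p_value = tst$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# covariates inside the sRAI score, excluded a priori from regression for
# collinearity with the exposure
SRAI_COMPONENT_VARS <- c("transplant_history", "d1_vasoactive",
                         "d1_mech_vent", "fb_percent", "d1_platelets")

#' Bivariate covariate screen
#'
#' Screens candidate covariates for association with an outcome flag at a
#' liberal threshold (default p < 0.15): Wilcoxon rank-sum for continuous
#' candidates, chi-square or Fisher for binary ones. Variables that are
#' components of the sRAI score are removed from the candidate list a
#' priori (collinearity with the exposure); constant variables are skipped
#' with a warning.
#'
#' @param data Analysis data frame (cohort joined with renal status).
#' @param outcome Name of the logical outcome column.
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Screening threshold, default 0.15.
#' @return Character vector of selected covariates, with the per-variable
#'   p-values attached as attribute `"screen"`.
#' @export
bivariate_screen <- function(data, outcome = "d3_severe_aki",
                             candidates = c("age", "male", "prism_iii",
                                            "persevere_ii", "baseline_scr",
                                            "d1_vis"),
                             alpha = 0.15) {
  banned <- intersect(candidates, SRAI_COMPONENT_VARS)
  if (length(banned)) {
    message("bivariate_screen: dropping sRAI-component covariate(s): ",
            paste(banned, collapse = ", "))
    candidates <- setdiff(candidates, banned)
  }
  g <- data[[outcome]]
  res <- lapply(candidates, function(v) two_group_p(data[[v]], g))
  p <- vapply(res, `[[`, numeric(1), "p")
  tests <- vapply(res, `[[`, character(1), "test")
  if (any(tests == "constant"))
    warning("bivariate_screen: constant candidate(s) skipped: ",
            paste(candidates[tests == "constant"], collapse = ", "),
            call. = FALSE)
  screen <- data.frame(variable = candidates, test = tests, p_value = p,
                       stringsAsFactors = FALSE)
  sel <- candidates[!is.na(p) & p < alpha]
  structure(sel, screen = screen)
}

#' Multivariable logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]) of a clinical outcome on an exposure and adjusting
#' covariates. Mirrors the published modelling choices: patients already
#' on kidney replacement therapy on Day 1 are excluded (their Day-1
#' creatinine is uninterpretable), and the PERSEVERE-II mortality
#' probability enters multiplied by 10. Complete separation is reported as
#' a diagnostic, never as silent coefficients.
#'
#' @param data Analysis data frame containing the outcome, covariates and
#'   (if `exclude_day1_krt`) a `krt_day1` flag plus `patient_id`.
#' @param outcome Name of the logical outcome column (e.g.
#'   `"d3_severe_aki"` or `"krt_day1_7"`).
#' @param covariates Character vector of model terms.
#' @param exclude_day1_krt Drop Day-1 KRT patients, default `TRUE`.
#' @param persevere_scale Multiplier applied to `persevere_ii`, default 10.
#' @param ci_level Confidence level for Wald intervals, default 0.95.
#' @return A list of class `srai_logit`: `table` (term, adjusted OR, CI,
#'   p), `n_used`, `excluded_ids`, `converged`, `separation_suspected`,
#'   `log_likelihood`, `max_abs_score` (gradient sup-norm at the optimum)
#'   and the underlying `fit`.
#' @export
fit_logistic <- function(data, outcome, covariates,
                         exclude_day1_krt = TRUE, persevere_scale = 10,
                         ci_level = 0.95) {
  excluded_ids <- character(0)
  if (exclude_day1_krt && !is.null(data$krt_day1)) {
    drop <- !is.na(data$krt_day1) & data$krt_day1
    excluded_ids <- if (!is.null(data$patient_id)) data$patient_id[drop]
                    else as.character(which(drop))
    data <- data[!drop, , drop = FALSE]
  }
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    abort("fit_logistic: outcome must have both classes after exclusions")
  if ("persevere_ii" %in% covariates && persevere_scale != 1) {
    data$persevere_ii_x10 <- data$persevere_ii * persevere_scale
    covariates[covariates == "persevere_ii"] <- "persevere_ii_x10"
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(covariates, collapse = " + ")))
  boundary_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        boundary_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  tab <- data.frame(term = rownames(cf),
                    or = exp(est),
                    ci_low = exp(est - z * se),
                    ci_high = exp(est + z * se),
                    p_value = cf[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  # score (gradient) of the log-likelihood at the fitted optimum
  mm <- stats::model.matrix(fit)
  resid_raw <- fit$y - fit$fitted.values
  score_vec <- drop(crossprod(mm, resid_raw))
  separation <- boundary_warning && (any(abs(est) > 12) || any(se > 50))
  structure(list(table = tab,
                 n_used = stats::nobs(fit),
                 excluded_ids = excluded_ids,
                 converged = fit$converged && !separation,
                 separation_suspected = separation,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 max_abs_score = max(abs(score_vec)),
                 fit = fit),
            class = "srai_logit")
}

#' @export
print.srai_logit <- function(x, ...) {
  cat("Logistic model (n =", x$n_used, ")\n")
  tab <- x$table
  tab$or <- signif(tab$or, 3)
  tab$ci_low <- signif(tab$ci_low, 3)
  tab$ci_high <- signif(tab$ci_high, 3)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  if (!x$converged) cat("WARNING: fit did not converge cleanly",
                        if (x$separation_suspected) "(separation suspected)",
                        "\n")
  invisible(x)
}
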