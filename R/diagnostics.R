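# Diagnostic test accuracy: 2x2 construction, sensitivity/specificity/
# predictive values with exact Clopper-Pearson intervals, likelihood
# ratios with log-method intervals, and nonparametric ROC analysis with
# DeLong variance and the paired DeLong test.

#' Build a 2x2 contingency table
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts; the total must be
#'   positive. `tp` counts classifier-positive patients with the outcome.
#' @return A list of class `srai_contingency` with the four cells and `n`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    abort("contingency_table: cells must be non-negative integers")
  if (sum(cells) <= 0) abort("contingency_table: table is empty")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n = as.integer(sum(cells))),
            class = "srai_contingency")
}

#' @export
print.srai_contingency <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"),
                              c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

#' Reconstruct a 2x2 table from published margins
#'
#' Given a cohort size, outcome count, classifier-positive count and true-
#' positive count, rebuilds the full table. This is how every published
#' table of the validation study is turned back into analyzable cells.
#'
#' @param n_total Cohort size.
#' @param n_outcome Patients with the outcome.
#' @param n_pred_pos Classifier-positive patients.
#' @param n_tp Classifier-positive patients with the outcome.
#' @return An `srai_contingency` table.
#' @export
contingency_from_margins <- function(n_total, n_outcome, n_pred_pos, n_tp) {
  tp <- n_tp
  fn <- n_outcome - n_tp
  fp <- n_pred_pos - n_tp
  tn <- n_total - tp - fn - fp
  if (any(c(tp, fp, fn, tn) < 0))
    abort("contingency_from_margins: margins are inconsistent ",
          "(a reconstructed cell is negative)")
  contingency_table(tp, fp, fn, tn)
}

#' Cross-classify predictions against outcomes
#'
#' @param predicted,truth Logical vectors of equal length, no missing
#'   values.
#' @return An `srai_contingency` table.
#' @export
contingency_from_labels <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth),
            !anyNA(predicted), !anyNA(truth))
  contingency_table(sum(predicted & truth), sum(predicted & !truth),
                    sum(!predicted & truth), sum(!predicted & !truth))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Equal-tailed exact interval by beta-quantile inversion of the binomial
#' tails.
#'
#' @param x Successes.
#' @param n Trials.
#' @param level Confidence level, default 0.95.
#' @return A numeric vector `c(lower, upper)` on the proportion scale.
#' @export
ci_clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

lr_ci <- function(lr, var_log, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(log(lr) + c(-1, 1) * z * sqrt(var_log))
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity, specificity, predictive values (Clopper-Pearson intervals)
#' and likelihood ratios (log-method intervals). A metric whose denominator
#' is zero, or a likelihood ratio with a zero numerator or denominator
#' cell, is returned as `NA` rather than raising, so batch reports stay
#' complete.
#'
#' @param table An `srai_contingency` table.
#' @param ci_level Confidence level, default 0.95.
#' @return A data frame with one row per metric (`sensitivity`,
#'   `specificity`, `ppv`, `npv`, `plr`, `nlr`): `estimate`, `ci_low`,
#'   `ci_high`. Proportions are on the 0-1 scale; likelihood ratios on the
#'   ratio scale.
#' @export
diagnostic_metrics <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "srai_contingency"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  prop <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(x / n, ci_clopper_pearson(x, n, ci_level))
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  ppv  <- prop(tp, tp + fp)
  npv  <- prop(tn, tn + fn)

  plr <- c(NA_real_, NA_real_, NA_real_)
  if (tp + fn > 0 && fp + tn > 0 && fp > 0 && tp > 0) {
    est <- (tp / (tp + fn)) / (fp / (fp + tn))
    v <- 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)
    plr <- c(est, lr_ci(est, v, ci_level))
  }
  nlr <- c(NA_real_, NA_real_, NA_real_)
  if (tp + fn > 0 && fp + tn > 0 && fn > 0 && tn > 0) {
    est <- (fn / (tp + fn)) / (tn / (fp + tn))
    v <- 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)
    nlr <- c(est, lr_ci(est, v, ci_level))
  }
  out <- rbind(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
               plr = plr, nlr = nlr)
  data.frame(metric = rownames(out), estimate = out[, 1],
             ci_low = out[, 2], ci_high = out[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# DeLong placement values via midranks: V10 per case (fraction of controls
# scored below, half credit for ties), V01 per control.
delong_placements <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Empirical AUROC with DeLong confidence interval
#'
#' Area under the empirical ROC curve by the Mann-Whitney construction
#' with half credit for ties (the trapezoid convention, stated explicitly
#' because renal angina scores take only twelve values), with the DeLong
#' placement-value variance.
#'
#' @param scores Numeric or ordinal classifier output, higher = more
#'   positive.
#' @param labels Logical outcome vector.
#' @param ci_level Confidence level, default 0.95.
#' @return A list with `auc`, `se`, `ci_low`, `ci_high` (Wald interval
#'   clipped to \[0, 1\]), `n_cases`, `n_controls`.
#' @export
empirical_auroc <- function(scores, labels, ci_level = 0.95) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    abort("empirical_auroc: both outcome classes must be present")
  p <- delong_placements(scores, labels)
  v <- if (p$m > 1) stats::var(p$v10) / p$m else NA_real_
  v <- v + if (p$n > 1) stats::var(p$v01) / p$n else NA_real_
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(auc = p$auc, se = se,
       ci_low = max(0, p$auc - z * se), ci_high = min(1, p$auc + z * se),
       n_cases = p$m, n_controls = p$n)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two classifiers evaluated on the same subjects,
#' using the DeLong covariance of placement values and a two-sided normal
#' approximation.
#'
#' @param scores_a,scores_b Classifier outputs on the same subjects.
#' @param labels Logical outcome vector.
#' @return A list with `auc_a`, `auc_b`, `delta_auc`, `var_delta`, `z`,
#'   `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    abort("delong_paired_test: inputs must have equal length")
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    abort("delong_paired_test: both outcome classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / pa$m + s01 / pa$n
  vd <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  delta <- pa$auc - pb$auc
  if (!is.finite(vd) || vd < .Machine$double.eps) {
    z <- 0
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else NA_real_
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
       var_delta = vd, z = z, p_value = p)
}
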