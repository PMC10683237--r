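# Diagnostic accuracy machinery: 2x2 reconstruction, exact intervals,
# likelihood ratios, empirical ROC and the DeLong test.

# brute-force AUROC: average over all case-control pairs with half credit
brute_auc <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force placement values by explicit double loops
brute_placements <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01)
}

test_that("2x2 tables rebuild exactly from published margins", {
  t1 <- contingency_from_margins(363, 79, 140, 67)
  expect_identical(unlist(t1[c("tp", "fp", "fn", "tn")], use.names = FALSE),
                   c(67L, 73L, 12L, 211L))
  t2 <- contingency_from_margins(363, 79, 253, 71)
  expect_identical(unlist(t2[c("tp", "fp", "fn", "tn")], use.names = FALSE),
                   c(71L, 182L, 8L, 102L))
  t3 <- contingency_from_margins(10, 0, 0, 0)
  expect_identical(t3$tn, 10L)
  expect_error(contingency_from_margins(10, 8, 9, 0), "inconsistent")
  expect_error(contingency_table(-1, 0, 0, 5), "non-negative")
})

test_that("Clopper-Pearson matches direct numeric inversion of the binomial tails", {
  invert <- function(x, n, level = 0.95) {
    a <- (1 - level) / 2
    lo <- if (x == 0) 0 else
      uniroot(function(p) 1 - pbinom(x - 1, n, p) - a, c(1e-12, 1 - 1e-12),
              tol = 1e-12)$root
    hi <- if (x == n) 1 else
      uniroot(function(p) pbinom(x, n, p) - a, c(1e-12, 1 - 1e-12),
              tol = 1e-12)$root
    c(lo, hi)
  }
  for (case in list(c(67, 79), c(211, 284), c(3, 10), c(0, 25), c(25, 25))) {
    got <- ci_clopper_pearson(case[1], case[2])
    expect_equal(unname(got), invert(case[1], case[2]), tolerance = 1e-8,
                 label = paste(case, collapse = "/"))
  }
  # the published sensitivity interval for 67/79 ("75-92" as percents)
  ci <- ci_clopper_pearson(67, 79)
  expect_equal(unname(ci), c(0.74969, 0.91897), tolerance = 1e-4)
  expect_identical(unname(fmt_ci(ci[1], ci[2], "pct")), "75-92")
})

test_that("diagnostic metrics reproduce the published sRAI row", {
  tab <- contingency_table(67, 73, 12, 211)
  m <- diagnostic_metrics(tab)
  g <- function(k) m$estimate[m$metric == k]
  expect_equal(g("sensitivity"), 67 / 79)
  expect_equal(g("specificity"), 211 / 284)
  expect_equal(g("ppv"), 67 / 140)
  expect_equal(g("npv"), 211 / 223)
  expect_equal(g("plr"), (67 / 79) / (73 / 284), tolerance = 1e-12)
  expect_equal(fmt_pct(g("sensitivity")), "85")
  expect_equal(fmt_pct(g("specificity")), "74")
  expect_equal(fmt_pct(g("ppv")), "48")
  expect_equal(fmt_pct(g("npv")), "95")
  expect_equal(fmt_ratio(g("plr")), "3.3")
})

test_that("undefined metrics are NA markers, not exceptions", {
  m <- diagnostic_metrics(contingency_table(79, 0, 0, 284))
  expect_equal(m$estimate[m$metric == "sensitivity"], 1)
  expect_equal(m$estimate[m$metric == "specificity"], 1)
  expect_true(is.na(m$estimate[m$metric == "plr"]))
  expect_true(is.na(m$estimate[m$metric == "nlr"]))
})

test_that("metrics satisfy Bayes consistency on exact fractions", {
  set.seed(3)
  for (i in 1:20) {
    cells <- rmultinom(1, 200, c(0.2, 0.3, 0.1, 0.4))[, 1] + 1L
    m <- diagnostic_metrics(contingency_table(cells[1], cells[2],
                                              cells[3], cells[4]))
    g <- function(k) m$estimate[m$metric == k]
    prev <- (cells[1] + cells[3]) / sum(cells)
    # posterior odds = prior odds x likelihood ratio
    expect_equal(g("ppv") / (1 - g("ppv")),
                 prev / (1 - prev) * g("plr"), tolerance = 1e-12)
  }
})

test_that("empirical AUROC equals brute-force pair counting", {
  # the worked 6-subject example: 8/9 concordant pairs
  expect_equal(empirical_auroc(1:6, c(F, F, T, F, T, T))$auc, 8 / 9)
  # perfectly separated and all-tied degenerate scores
  expect_equal(empirical_auroc(c(1, 2, 9, 10), c(F, F, T, T))$auc, 1)
  expect_equal(empirical_auroc(rep(2, 10), rep(c(F, T), 5))$auc, 0.5)
  # exhaustive scan of every labelling at n <= 8 with coarse tied scores
  set.seed(7)
  for (n in 4:8) {
    scores <- sample(1:3, n, replace = TRUE)
    for (mask in 1:(2^n - 2)) {
      labels <- as.logical(bitwAnd(bitwShiftL(1, 0:(n - 1)), mask))
      if (!any(labels) || all(labels)) next
      expect_equal(empirical_auroc(scores, labels)$auc,
                   brute_auc(scores, labels))
    }
  }
  # random instances at n = 50
  for (i in 1:100) {
    scores <- sample(1:12, 50, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(0.3, 0.7))
    if (!any(labels) || all(labels)) next
    expect_equal(empirical_auroc(scores, labels)$auc,
                 brute_auc(scores, labels))
  }
  expect_error(empirical_auroc(1:4, rep(TRUE, 4)), "both")
})

test_that("a binary predictor's AUROC equals (sens + spec) / 2 exactly", {
  co <- small_cohort(500)
  st <- renal_status(co)
  sc <- score_cohort(co, st)
  aki <- st$d3_severe_aki
  tab <- contingency_from_labels(sc$srai_positive, aki)
  sens <- tab$tp / (tab$tp + tab$fn)
  spec <- tab$tn / (tab$tn + tab$fp)
  expect_equal(empirical_auroc(as.numeric(sc$srai_positive), aki)$auc,
               (sens + spec) / 2)
})

test_that("DeLong placements and variance match brute force on small inputs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    scores <- sample(1:4, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    bp <- brute_placements(scores, labels)
    a <- empirical_auroc(scores, labels)
    m <- sum(labels); nn <- sum(!labels)
    v_brute <- (if (m > 1) var(bp$v10) / m else NA) +
      (if (nn > 1) var(bp$v01) / nn else NA)
    expect_equal(a$auc, mean(bp$v10))
    if (is.finite(v_brute)) expect_equal(a$se^2, v_brute, tolerance = 1e-12)
  }
})

test_that("AUROC and DeLong agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  co <- small_cohort(400, seed = 9)
  st <- renal_status(co)
  sc <- score_cohort(co, st)
  aki <- st$d3_severe_aki
  mine <- empirical_auroc(sc$rai_score, aki)
  ref <- pROC::roc(response = aki, predictor = sc$rai_score,
                   direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(mine$ci_low, mine$ci_high), ref_ci[c(1, 3)],
               tolerance = 1e-6)
  other <- pROC::roc(response = aki, predictor = st$d1_scr_ratio,
                     direction = "<", quiet = TRUE)
  ref_test <- pROC::roc.test(ref, other, method = "delong", paired = TRUE)
  mine_test <- delong_paired_test(sc$rai_score, st$d1_scr_ratio, aki)
  expect_equal(mine_test$p_value, ref_test$p.value, tolerance = 1e-6)
})

test_that("the paired DeLong test detects a true AUC difference", {
  # classifier a separates cases by a 0.507 SD shift (AUC ~ 0.64),
  # classifier b is pure noise (AUC 0.5); at 500 subjects per class the
  # test should reject far more often than not
  set.seed(31)
  rejections <- vapply(1:60, function(i) {
    labels <- rep(c(TRUE, FALSE), each = 500)
    a <- rnorm(1000) + 0.507 * labels
    b <- rnorm(1000)
    delong_paired_test(a, b, labels)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("the paired DeLong test is exact-null on identical scores", {
  set.seed(2)
  s <- rnorm(40)
  l <- rep(c(TRUE, FALSE), 20)
  res <- delong_paired_test(s, s, l)
  expect_equal(res$delta_auc, 0)
  expect_equal(res$p_value, 1)
  expect_error(delong_paired_test(s, s[-1], l), "equal length")
})
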