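# Relative risks, group comparisons, covariate screening, logistic models.

test_that("relative risks reproduce every published point estimate and CI string", {
  fmt <- function(rr) c(fmt_ratio(rr$rr), fmt_ci(rr$ci_low, rr$ci_high, "ratio"))
  # D3 severe AKI by sRAI: 67/140 vs 12/223
  expect_identical(fmt(relative_risk(67, 140, 12, 223)), c("8.9", "5-16"))
  # KRT by sRAI: 45/140 vs 4/223
  expect_identical(fmt(relative_risk(45, 140, 4, 223)), c("18", "6.6-49"))
  # mortality by sRAI: 16/140 vs 10/223
  expect_identical(fmt(relative_risk(16, 140, 10, 223)), c("2.5", "1.2-5.5"))
  # AKI risk, sRAI+ versus D1SCr+: 67/140 vs 71/253
  expect_identical(fmt(relative_risk(67, 140, 71, 253)), c("1.7", "1.3-2.2"))
  # mortality by AKI status: 15/79 vs 11/284
  expect_identical(fmt_ratio(relative_risk(15, 79, 11, 284)$rr), "4.9")
})

test_that("relative risk edge cases: equal risks and empty reference arm", {
  expect_equal(relative_risk(10, 100, 20, 200)$rr, 1.0)
  inf <- relative_risk(5, 50, 0, 60)
  expect_identical(inf$rr, Inf)
  expect_true(inf$undefined_ci)
})

test_that("group comparison reproduces the published mortality chi-square", {
  # 28-day mortality by sRAI group: 16/140 vs 10/223, uncorrected
  # chi-square p printed as 0.013
  g <- rep(c(TRUE, FALSE), c(140, 223))
  x <- c(rep(c(TRUE, FALSE), c(16, 124)), rep(c(TRUE, FALSE), c(10, 213)))
  tab <- compare_groups(data.frame(g = g, x = x), "g")
  expect_identical(tab$test, "chisq")
  expect_equal(round(tab$p_value, 3), 0.013)
})

test_that("group comparison picks tests by type and expected counts", {
  set.seed(4)
  d <- data.frame(g = rep(c(TRUE, FALSE), each = 100),
                  cont = rnorm(200),
                  rare = c(rep(TRUE, 2), rep(FALSE, 198)))
  tab <- compare_groups(d, "g", c("cont", "rare"))
  expect_identical(tab$test, c("wilcoxon", "fisher"))
  # identical groups: exact test p = 1
  d2 <- data.frame(g = rep(c(TRUE, FALSE), each = 20),
                   flag = rep(c(TRUE, FALSE), 20))
  expect_equal(compare_groups(d2, "g", "flag")$p_value, 1)
  # a 5-point location shift at n = 200/arm is always detected
  for (seed in 1:5) {
    set.seed(seed)
    d3 <- data.frame(g = rep(c(TRUE, FALSE), each = 200),
                     y = rnorm(400) + 5 * rep(c(1, 0), each = 200))
    expect_lt(compare_groups(d3, "g", "y")$p_value, 0.001)
  }
})

test_that("bivariate screen selects what differs and bans sRAI components", {
  # construct a cohort where only prism_iii differs between outcome groups
  set.seed(8)
  n <- 400
  out <- rep(c(TRUE, FALSE), each = n / 2)
  d <- data.frame(d3_severe_aki = out,
                  age = rnorm(n, 10, 4),
                  male = runif(n) < 0.5,
                  prism_iii = rpois(n, 8 + 6 * out),
                  persevere_ii = runif(n, 0, 0.4),
                  baseline_scr = rlnorm(n, log(0.36), 0.3),
                  d1_vis = rlnorm(n, 2, 0.6))
  sel <- bivariate_screen(d, alpha = 0.01)
  expect_identical(as.character(sel), "prism_iii")
  # alpha = 1 admits every non-constant candidate
  sel_all <- bivariate_screen(d, alpha = 1)
  expect_setequal(as.character(sel_all),
                  c("age", "male", "prism_iii", "persevere_ii",
                    "baseline_scr", "d1_vis"))
  # sRAI-internal covariates are dropped a priori
  d$d1_platelets <- rnorm(n, 150, 50)
  expect_message(
    sel2 <- bivariate_screen(d, candidates = c("prism_iii", "d1_platelets",
                                               "transplant_history")),
    "d1_platelets")
  expect_false("d1_platelets" %in% sel2)
  # constant candidates are skipped with a warning
  d$const <- 1
  expect_warning(bivariate_screen(d, candidates = c("prism_iii", "const")),
                 "constant")
})

test_that("default screen admits the published covariate set on most seeds", {
  hits <- 0L
  for (seed in 1:7) {
    co <- suppressWarnings(generate_cohort(cohort_config(n = 2000, seed = seed)))
    st <- renal_status(co)
    d <- cbind(co, st[, c("baseline_scr", "d3_severe_aki")])
    sel <- as.character(bivariate_screen(d))
    if (all(c("prism_iii", "persevere_ii", "baseline_scr", "d1_vis") %in% sel))
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("single-covariate logistic OR equals the 2x2 cross-product ratio", {
  set.seed(21)
  x <- runif(500) < 0.4
  y <- runif(500) < ifelse(x, 0.45, 0.15)
  d <- data.frame(y = y, x = x)
  fit <- fit_logistic(d, "y", "x", exclude_day1_krt = FALSE)
  cpr <- (sum(x & y) * sum(!x & !y)) / (sum(x & !y) * sum(!x & y))
  expect_equal(fit$table$or[fit$table$term == "xTRUE"], cpr,
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$max_abs_score, 1e-6)
})

test_that("a saturated two-covariate fit matches hand-computed log-odds", {
  # 2x2x2 cell counts; saturated model (with interaction) reproduces each
  # cell's empirical logit exactly
  counts <- array(c(30, 10, 20, 25, 12, 28, 9, 33), dim = c(2, 2, 2),
                  dimnames = list(y = c("1", "0"), a = c("0", "1"),
                                  b = c("0", "1")))
  d <- do.call(rbind, lapply(1:2, function(a) do.call(rbind, lapply(1:2,
    function(b) do.call(rbind, lapply(1:2, function(y)
      data.frame(y = y == 1, a = a == 2, b = b == 2)[
        rep(1, counts[y, a, b]), ]))))))
  fit <- fit_logistic(d, "y", c("a", "b", "a:b"), exclude_day1_krt = FALSE)
  cf <- coef(fit$fit)
  logit <- function(a, b) log(counts[1, a + 1, b + 1] / counts[2, a + 1, b + 1])
  expect_equal(unname(cf["(Intercept)"]), logit(0, 0), tolerance = 1e-7)
  expect_equal(unname(cf["aTRUE"]), logit(1, 0) - logit(0, 0), tolerance = 1e-7)
  expect_equal(unname(cf["bTRUE"]), logit(0, 1) - logit(0, 0), tolerance = 1e-7)
  expect_equal(unname(cf["aTRUE:bTRUE"]),
               logit(1, 1) - logit(1, 0) - logit(0, 1) + logit(0, 0),
               tolerance = 1e-7)
  expect_lt(fit$max_abs_score, 1e-6)
})

test_that("logistic fit applies the Day-1 KRT exclusion and PERSEVERE scaling", {
  co <- small_cohort(600, seed = 13)
  st <- renal_status(co)
  d <- cbind(co, st[, c("baseline_scr", "d3_severe_aki")])
  fit <- fit_logistic(d, "d3_severe_aki",
                      c("prism_iii", "persevere_ii", "baseline_scr"),
                      exclude_day1_krt = TRUE)
  expect_identical(fit$n_used, nrow(d) - sum(d$krt_day1))
  expect_setequal(fit$excluded_ids, d$patient_id[d$krt_day1])
  expect_true("persevere_ii_x10" %in% fit$table$term)
  # scaling by 10 divides the log-OR by 10, so OR_x10 = OR^(1/10)
  fit_raw <- fit_logistic(d, "d3_severe_aki",
                          c("prism_iii", "persevere_ii", "baseline_scr"),
                          exclude_day1_krt = TRUE, persevere_scale = 1)
  or10 <- fit$table$or[fit$table$term == "persevere_ii_x10"]
  or1 <- fit_raw$table$or[fit_raw$table$term == "persevere_iiTRUE" |
                            fit_raw$table$term == "persevere_ii"]
  expect_equal(or10^10, or1, tolerance = 1e-6)
})

test_that("complete separation is reported, never silent", {
  d <- data.frame(y = rep(c(TRUE, FALSE), each = 25),
                  x = rep(c(TRUE, FALSE), each = 25))
  fit <- suppressWarnings(fit_logistic(d, "y", "x",
                                       exclude_day1_krt = FALSE))
  expect_true(fit$separation_suspected)
  expect_false(fit$converged)
})
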