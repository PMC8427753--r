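test_that("confusion metrics reproduce the development-cohort 2x2 and scale invariance", {
  cm <- confusion_metrics(tp = 28, fn = 9, fp = 8, tn = 63)
  expect_equal(round(cm$sensitivity, 3), 0.757)
  expect_equal(round(cm$specificity, 3), 0.887)
  expect_equal(round(cm$youden, 3), 0.644)
  expect_equal(cm$odds_ratio, (28 * 63) / (8 * 9))  # 24.5 by hand

  perfect <- confusion_metrics(5, 0, 0, 5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$youden, 1)
  expect_true("odds_ratio" %in% perfect$undefined)

  for (k in c(2L, 7L)) {
    scaled <- confusion_metrics(28L * k, 9L * k, 8L * k, 63L * k)
    expect_equal(scaled$sensitivity, cm$sensitivity)
    expect_equal(scaled$specificity, cm$specificity)
    expect_equal(scaled$youden, cm$youden)
    expect_equal(scaled$odds_ratio, cm$odds_ratio)
  }
  expect_error(confusion_metrics(1, -1, 0, 2), "non-negative")
})

test_that("confusion metrics accept a 2x2 matrix and flag zero denominators", {
  cm <- confusion_metrics(rbind(c(28, 9), c(8, 63)))
  expect_equal(round(cm$youden, 3), 0.644)
  nd <- confusion_metrics(0, 0, 3, 7)
  expect_true(all(c("sensitivity", "youden") %in% nd$undefined))
  expect_true(is.na(nd$sensitivity))
})

test_that("univariate comparison routes tests and handles degenerate input", {
  set.seed(5)
  x <- rnorm(40)
  d <- data.frame(v = c(x, x), g = rep(c("a", "b"), each = 40))
  res <- univariate_compare(d, "v", "g")
  expect_identical(res$test_name, "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  dsk <- data.frame(v = c(rexp(30)^3, rexp(30)^3 + 2),
                    g = rep(c("a", "b"), each = 30))
  expect_identical(univariate_compare(dsk, "v", "g")$test_name, "mann_whitney")

  dbal <- data.frame(v = c("x", "y", "x", "y"), g = c("a", "a", "b", "b"))
  resf <- univariate_compare(dbal, "v", "g")
  expect_identical(resf$test_name, "fisher_exact")
  expect_equal(resf$p, 1)

  dcon <- data.frame(v = rep(1, 20), g = rep(c("a", "b"), 10))
  expect_error(univariate_compare(dcon, "v", "g"), "constant")
})

test_that("chi-square routing and statistic match the hand oracle", {
  tab <- rbind(c(28, 9), c(8, 63))
  res <- contingency_analysis(tab)
  expect_identical(res$test_name, "pearson_chisq")
  expect_equal(res$statistic, chisq_oracle(tab))
  expect_lt(res$p, 0.001)

  # good-collateral by TOAST counts: association significant
  toast_tab <- rbind(c(10, 49), c(23, 21))
  res2 <- contingency_analysis(toast_tab)
  expect_equal(res2$statistic, chisq_oracle(toast_tab))
  expect_lt(res2$p, 0.05)

  expect_equal(contingency_analysis(rbind(c(5, 5), c(5, 5)))$statistic, 0)
  expect_equal(contingency_analysis(rbind(c(5, 5), c(5, 5)))$p, 1)
  expect_lt(contingency_analysis(rbind(c(0, 10), c(10, 0)))$p, 1e-4)
  expect_identical(contingency_analysis(rbind(c(1, 1), c(1, 1)))$test_name,
                   "fisher_exact")
  expect_error(contingency_analysis(rbind(c(0, 0), c(1, 2))), "empty margin")
})

test_that("random r x c tables match the textbook chi-square oracle", {
  set.seed(21)
  for (i in 1:20) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 12) + 5, r, cc)
    expect_equal(contingency_analysis(tab)$statistic, chisq_oracle(tab))
  }
})

test_that("one-covariate logistic OR equals the 2x2 cross-ratio", {
  # reconstruct the 108 patient-level records from the development 2x2
  d <- data.frame(
    good = rep(c(TRUE, TRUE, FALSE, FALSE), c(28, 8, 9, 63)),
    fav = rep(c(TRUE, FALSE, TRUE, FALSE), c(28, 8, 9, 63)))
  m <- fit_logistic(d, "fav", "good", "saturated")
  or <- m$coefficients$or[m$coefficients$term == "goodTRUE"]
  expect_equal(or, 24.5, tolerance = 1e-4)

  set.seed(31)
  for (i in 1:10) {
    tab <- matrix(sample(5:40, 4, replace = TRUE), 2)
    di <- data.frame(
      x = rep(c(TRUE, TRUE, FALSE, FALSE), tab),
      y = rep(c(TRUE, FALSE, TRUE, FALSE), tab))
    mi <- fit_logistic(di, "y", "x")
    expect_equal(mi$coefficients$or[2], (tab[1] * tab[4]) / (tab[2] * tab[3]),
                 tolerance = 1e-4)
  }
})

test_that("logistic fit rejects degenerate outcomes and separation", {
  d <- data.frame(x = rnorm(30), y = rep(TRUE, 30))
  expect_error(fit_logistic(d, "y", "x"), "both outcome classes")
  dsep <- data.frame(x = c(rnorm(25, -4), rnorm(25, 4)),
                     y = rep(c(FALSE, TRUE), each = 25))
  suppressWarnings(expect_error(fit_logistic(dsep, "y", "x"), "separation"))
  dcon <- data.frame(x = rep(1, 30), y = rep(c(TRUE, FALSE), 15))
  expect_error(fit_logistic(dcon, "y", "x"), "constant")
})

test_that("logistic Wald intervals bracket the OR and AUC is in range", {
  set.seed(9)
  n <- 400
  x <- rnorm(n); z <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x + 0.6 * z))
  d <- data.frame(x = x, z = factor(z), y = y)
  m <- fit_logistic(d, "y", c("x", "z"), "sim")
  expect_true(all(m$coefficients$ci_low <= m$coefficients$or &
                  m$coefficients$or <= m$coefficients$ci_high))
  expect_gte(m$auc, 0.5)
  expect_lte(m$auc, 1)
})

test_that("ROC handles the degenerate and perfectly separated extremes", {
  expect_error(roc_analysis(1:5, rep(1, 5)), "both outcome classes")
  expect_warning(rc <- roc_analysis(rep(2, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(rc$auc, 0.5)

  rs <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(rs$auc, 1)
  expect_equal(rs$youden, 1)
  expect_gt(rs$cutoff, 3); expect_lt(rs$cutoff, 11)
})

test_that("trapezoid AUC equals brute-force concordance, ties included", {
  scores <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  y <- c(0, 0, 1, 0, 1, 0, 1, 0, 1, 1)
  rc <- roc_analysis(scores, y)
  expect_equal(rc$auc, concordance_auc(scores, y))

  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    sc <- sample(1:8, n, replace = TRUE) + round(rnorm(n), 1)
    yy <- rbinom(n, 1, 0.5)
    if (length(unique(yy)) < 2 || length(unique(sc)) < 2) next
    rr <- roc_analysis(sc, yy)
    expect_equal(rr$auc, concordance_auc(sc, yy), tolerance = 1e-12)
    # Youden identity at the selected cutoff
    expect_equal(rr$youden, rr$sensitivity + rr$specificity - 1,
                 tolerance = 1e-12)
    # DeLong interval brackets the point estimate (variance can degenerate
    # to NaN on tiny single-case samples)
    if (all(is.finite(rr$auc_ci))) {
      expect_true(rr$auc_ci[1] <= rr$auc + 1e-12 && rr$auc <= rr$auc_ci[2] + 1e-12)
    }
  }
})

test_that("Youden ties break toward the higher-specificity cutoff", {
  # two cutoffs reach Youden 0.5: sens 1/spec .5 and sens .5/spec 1
  rc <- roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(rc$specificity, 1)
  expect_gt(rc$cutoff, 3)
})

test_that("inter-rater reliability covers both modes and matches oracles", {
  a1 <- c(10.2, 33.0, 47.5, 58.1, 81.0, 62.4)
  a2 <- c(14.0, 30.5, 50.0, 61.2, 78.8, 60.0)
  expect_equal(interrater_reliability(a1, a1, "continuous_angle"), 1)
  expect_equal(interrater_reliability(0:4, 0:4, "ordinal_grade"), 1)
  # frozen oracle: two-way absolute-agreement single-measure ICC computed
  # with an independent implementation
  expect_equal(interrater_reliability(a1, a2, "continuous_angle"),
               0.9931887371326362, tolerance = 1e-9)
  # frozen oracle: linearly weighted kappa, independent implementation
  r1 <- c(0, 1, 2, 3, 4, 2); r2 <- c(1, 1, 2, 4, 4, 2)
  expect_equal(interrater_reliability(r1, r2, "ordinal_grade"),
               10 / 13, tolerance = 1e-12)
  expect_equal(interrater_reliability(r1, r2, "ordinal_grade"),
               weighted_kappa_oracle(r1, r2, 0:4), tolerance = 1e-12)
  # one rater constant: agreement equals chance, kappa 0
  expect_equal(interrater_reliability(rep(2, 6), c(0:4, 2), "ordinal_grade"), 0)
  # absolute agreement penalizes a constant shift
  expect_lt(interrater_reliability(a1, a1 + 5, "continuous_angle"), 1)
  expect_error(interrater_reliability(rep(1, 5), rep(1, 5)), "zero variance")
})
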