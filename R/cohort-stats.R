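# Statistical pipeline for EVT cohorts scored with the ABZA grading:
# diagnostic 2x2 metrics, univariate group comparisons, enter-method logistic
# models, empirical ROC with Youden cutoff, contingency analyses and
# inter-rater reliability.

#' Diagnostic metrics from a 2x2 confusion table
#'
#' Positive test = good collaterals (grade above the dichotomy threshold);
#' positive state = favorable outcome (mRS <= 2 at 90 days). A metric whose
#' denominator is zero is reported as `NA` and listed in `undefined` rather
#' than propagating silently.
#'
#' @param tp,fn,fp,tn Non-negative integer cell counts; alternatively `tp`
#'   may be a 2x2 matrix `rbind(c(tp, fn), c(fp, tn))`.
#' @return A list of class `confusion_metrics`: `sensitivity`, `specificity`,
#'   `youden` (sensitivity + specificity - 1), `odds_ratio`
#'   (tp*tn / (fp*fn)), `counts`, `undefined`.
#' @export
#' @examples
#' confusion_metrics(tp = 28, fn = 9, fp = 8, tn = 63)
confusion_metrics <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.matrix(tp)) {
    stopifnot(identical(dim(tp), c(2L, 2L)))
    fn <- tp[1, 2]; fp <- tp[2, 1]; tn <- tp[2, 2]; tp <- tp[1, 1]
  }
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion table cells must be non-negative integer counts", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty confusion table", call. = FALSE)
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  youden <- if (!is.na(sens) && !is.na(spec)) sens + spec - 1 else {
    undefined <- c(undefined, "youden"); NA_real_
  }
  or <- if (fp > 0 && fn > 0) (tp * tn) / (fp * fn) else {
    undefined <- c(undefined, "odds_ratio"); NA_real_
  }
  structure(list(sensitivity = sens, specificity = spec, youden = youden,
                 odds_ratio = or, counts = cells, undefined = undefined),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> sens %.3f, spec %.3f, Youden %.3f, OR %.3g\n",
              x$sensitivity, x$specificity, x$youden, x$odds_ratio))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Univariate comparison of one variable between two outcome groups
#'
#' Continuous variables are screened for normality (Shapiro-Wilk at 0.05 in
#' each group) and routed to a two-sample t-test when both groups pass, a
#' Mann-Whitney U test otherwise. Categorical variables get a Pearson
#' chi-square, switching to Fisher's exact test when any expected cell count
#' falls below 5. Missing values are dropped complete-case and the exclusion
#' count reported.
#'
#' @param data A data.frame.
#' @param variable Column name of the variable to compare.
#' @param group Column name of the two-level grouping (the outcome dichotomy).
#' @param type `"auto"` (numeric with > 5 distinct values is continuous),
#'   `"continuous"` or `"categorical"`.
#' @return A list: `variable`, `test_name`, `statistic`, `p`, `n_used`,
#'   `n_excluded`.
#' @export
univariate_compare <- function(data, variable, group, type = c("auto", "continuous", "categorical")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(data), variable %in% names(data), group %in% names(data))
  x <- data[[variable]]
  g <- data[[group]]
  keep <- !is.na(x) & !is.na(g)
  n_excluded <- sum(!keep)
  x <- x[keep]; g <- as.factor(as.character(g[keep]))
  if (nlevels(g) != 2L) stop("group must have exactly two observed levels", call. = FALSE)
  if (any(table(g) < 2L)) stop("need at least 2 observations per group", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate test: variable '", variable, "' is constant after ",
         "missing-data removal", call. = FALSE)
  }
  if (type == "auto") {
    type <- if (is.numeric(x) && length(unique(x)) > 5L) "continuous" else "categorical"
  }
  if (type == "continuous") {
    if (!is.numeric(x)) stop("continuous comparison requires a numeric variable", call. = FALSE)
    normal <- vapply(split(x, g), function(v) {
      if (length(v) < 3L || length(unique(v)) == 1L) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }, TRUE)
    if (all(normal)) {
      ht <- stats::t.test(x ~ g, var.equal = TRUE)
      out <- list(test_name = "t", statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x ~ g))
      out <- list(test_name = "mann_whitney", statistic = unname(ht$statistic),
                  p = ht$p.value)
    }
  } else {
    tab <- table(x, g)
    out <- contingency_test_core(tab)
  }
  c(list(variable = variable), out,
    list(n_used = length(x), n_excluded = n_excluded))
}

contingency_test_core <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty margin", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == 2L) && any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    list(test_name = "fisher_exact", statistic = NA_real_, p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test_name = "pearson_chisq", statistic = unname(ht$statistic),
         p = ht$p.value)
  }
}

#' Pearson chi-square / Fisher analysis of an r x c contingency table
#'
#' Pearson chi-square without continuity correction on the full table, with a
#' Fisher exact fallback for 2x2 tables with any expected count below 5 --
#' used for the mRS-by-collateral-class and grading-by-TOAST comparisons.
#'
#' @param table Matrix (or table) of non-negative counts.
#' @return A list: `test_name`, `statistic` (`NA` for Fisher), `df`, `p`,
#'   `expected`.
#' @export
#' @examples
#' contingency_analysis(rbind(c(28, 9), c(8, 63)))
contingency_analysis <- function(table) {
  tab <- as.matrix(table)
  if (anyNA(tab) || any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("empty contingency table", call. = FALSE)
  core <- contingency_test_core(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  df <- if (core$test_name == "pearson_chisq") (nrow(tab) - 1L) * (ncol(tab) - 1L) else NA_integer_
  c(core[c("test_name", "statistic")], list(df = df), core["p"],
    list(expected = expected))
}

#' Enter-method logistic regression with odds ratios and Wald intervals
#'
#' Fits a maximum-likelihood logistic model entering all listed covariates
#' simultaneously, the modelling scheme used for the 90-day prognosis models
#' (Model 1 keeps the ABZA dichotomy and drops the ASITN/SIR comparator;
#' Model 2 the reverse, since the two collateral scores are collinear by
#' design). Reports per-covariate odds ratios with Wald 95% confidence
#' intervals and Wald p-values, plus the model AUC (trapezoid over fitted
#' probabilities) with a DeLong interval.
#'
#' @param data A data.frame.
#' @param outcome Column name of a binary outcome (logical, 0/1, or
#'   two-level factor; the second level / `TRUE` / `1` is the event, here
#'   favorable mRS <= 2).
#' @param covariates Character vector of covariate column names; factors are
#'   expanded to treatment contrasts against their first level.
#' @param model_label Free-text label carried into the result.
#' @return An object of class `abza_logistic`: `coefficients` data.frame
#'   (term, estimate, or, ci_low, ci_high, p), `auc`, `auc_ci`, `fit` (the
#'   underlying `glm`), `model_label`, `n`.
#' @export
fit_logistic <- function(data, outcome, covariates, model_label = "Model 1") {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(covariates %in% names(data)), length(covariates) >= 1L)
  d <- data[, c(outcome, covariates), drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  y <- to_binary(d[[outcome]], outcome)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: both outcome classes must be present", call. = FALSE)
  }
  for (v in covariates) {
    vals <- d[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      stop("covariate '", v, "' is constant in the analysis sample", call. = FALSE)
    }
  }
  d$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iter,
         " IRLS iterations; check covariate scaling or separation", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  if (any(abs(cf[, "Estimate"]) > 15) || any(cf[, "Std. Error"] > 100)) {
    stop("complete or quasi-separation detected (diverging coefficients); ",
         "a larger or less extreme sample is needed for a stable fit", call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = rownames(cf),
                      estimate = cf[, "Estimate"],
                      or = exp(cf[, "Estimate"]),
                      ci_low = exp(cf[, "Estimate"] - z * cf[, "Std. Error"]),
                      ci_high = exp(cf[, "Estimate"] + z * cf[, "Std. Error"]),
                      p = cf[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  roc <- roc_analysis(stats::fitted(fit), y)
  structure(list(coefficients = coefs, auc = roc$auc, auc_ci = roc$auc_ci,
                 fit = fit, model_label = model_label, n = nrow(d),
                 n_excluded = sum(!keep)),
            class = "abza_logistic")
}

to_binary <- function(y, what) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("outcome '", what, "' must have two levels", call. = FALSE)
    return(as.integer(y == levels(y)[2L]))
  }
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  if (is.character(y) && length(unique(y)) == 2L) {
    return(as.integer(y == sort(unique(y))[2L]))
  }
  stop("outcome '", what, "' must be binary", call. = FALSE)
}

#' @export
print.abza_logistic <- function(x, digits = 3, ...) {
  cat(sprintf("<abza_logistic> %s (n = %d, enter method)\n", x$model_label, x$n))
  out <- x$coefficients
  out$or <- signif(out$or, digits)
  out$ci_low <- signif(out$ci_low, digits)
  out$ci_high <- signif(out$ci_high, digits)
  out$p <- signif(out$p, digits)
  print(out[, c("term", "or", "ci_low", "ci_high", "p")], row.names = FALSE)
  cat(sprintf("  model AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc,
              x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Empirical ROC analysis with Youden-index cutoff selection
#'
#' Scans cutoffs at the midpoints between sorted unique score values (plus
#' one cutoff below the minimum and one above the maximum), predicting a
#' favorable outcome when score > cutoff. The AUC is the trapezoid area under
#' the empirical curve -- equal to the concordance probability with ties
#' counted 1/2 -- with a DeLong 95% confidence interval. The optimal cutoff
#' maximizes the Youden index; exact ties are broken toward the higher
#' cutoff, i.e. toward higher specificity.
#'
#' @param scores Numeric per-patient scores (e.g. ABZA degrees); higher
#'   scores must indicate the favorable state.
#' @param outcomes Binary outcome (logical, 0/1 or two-level factor).
#' @return An object of class `roc_result`: `auc`, `auc_ci`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, and the scanned `curve`
#'   data.frame (cutoff, sensitivity, specificity).
#' @export
roc_analysis <- function(scores, outcomes) {
  y <- to_binary(outcomes, "outcomes")
  stopifnot(is.numeric(scores), length(scores) == length(y))
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("ROC analysis needs both outcome classes present", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    warning("constant scores: ROC curve is the diagonal, AUC = 0.5")
    return(structure(list(auc = 0.5, auc_ci = c(NA_real_, NA_real_),
                          cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, youden = NA_real_,
                          curve = NULL),
                     class = "roc_result"))
  }
  u <- sort(unique(scores))
  cutoffs <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  sens <- vapply(cutoffs, function(ct) sum(scores > ct & y == 1) / npos, 0)
  spec <- vapply(cutoffs, function(ct) sum(scores <= ct & y == 0) / nneg, 0)
  # trapezoid over (FPR, TPR), curve ordered from all-positive to all-negative
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  proc_obj <- suppressMessages(pROC::roc(response = y, predictor = scores,
                                         direction = "<", quiet = TRUE))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(proc_obj, method = "delong")))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]   # ties toward higher specificity
  structure(list(auc = auc, auc_ci = ci[c(1, 3)], cutoff = cutoffs[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = youden[best],
                 curve = data.frame(cutoff = cutoffs, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc,
              x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden-optimal cutoff %.3g: sens %.3f, spec %.3f, Youden %.3f\n",
              x$cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Inter-rater reliability of ABZA measurements or grades
#'
#' For continuous angle readings, the two-way random-effects
#' absolute-agreement single-measure intraclass correlation ICC(A,1); for
#' ordinal grades, linearly weighted Cohen's kappa. The study literature
#' reports a single unnamed "IRR" coefficient, so both conventions are
#' offered.
#'
#' @param rater1,rater2 Numeric rating vectors of equal length (>= 2
#'   patients rated by both).
#' @param mode `"continuous_angle"` (ICC) or `"ordinal_grade"` (weighted
#'   kappa).
#' @return The reliability coefficient (numeric scalar).
#' @export
interrater_reliability <- function(rater1, rater2,
                                   mode = c("continuous_angle", "ordinal_grade")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(rater1), is.numeric(rater2),
            length(rater1) == length(rater2))
  keep <- !is.na(rater1) & !is.na(rater2)
  r1 <- rater1[keep]; r2 <- rater2[keep]
  n <- length(r1)
  if (n < 2L) stop("need at least 2 patients rated by both raters", call. = FALSE)
  if (length(unique(r1)) == 1L && length(unique(r2)) == 1L) {
    stop("undefined reliability coefficient: zero variance in both raters",
         call. = FALSE)
  }
  if (mode == "continuous_angle") icc_a1(r1, r2) else weighted_kappa(r1, r2)
}

# ICC(A,1): two-way ANOVA (subjects x raters, no interaction),
# (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
icc_a1 <- function(r1, r2) {
  x <- cbind(r1, r2)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-300) {
    stop("undefined reliability coefficient: zero variance in both raters",
         call. = FALSE)
  }
  (msr - mse) / denom
}

# Cohen's kappa with linear weights w = 1 - |i - j| / (max - min) over the
# combined rating range.
weighted_kappa <- function(r1, r2) {
  lev <- sort(unique(c(r1, r2)))
  rng <- max(lev) - min(lev)
  if (rng == 0) {
    stop("undefined reliability coefficient: zero variance in both raters",
         call. = FALSE)
  }
  w <- 1 - abs(outer(lev, lev, "-")) / rng
  f1 <- factor(r1, levels = lev); f2 <- factor(r2, levels = lev)
  obs <- table(f1, f2) / length(r1)
  exp_tab <- outer(rowSums(obs), colSums(obs))
  po <- sum(w * obs); pe <- sum(w * exp_tab)
  if (abs(1 - pe) < 1e-300) {
    stop("undefined reliability coefficient: chance-expected agreement is 1",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}
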