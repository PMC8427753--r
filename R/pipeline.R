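# End-to-end pipeline: measure -> grade -> analyze, with persisted outputs.

#' Run the full prognostic analysis on a graded cohort
#'
#' Reproduces the analysis pipeline of the development study on any cohort
#' table: univariate comparisons of baseline and EVT variables between the
#' favorable (mRS <= `outcome_cutoff`) and unfavorable groups; enter-method
#' logistic models (Model 1 with the ABZA dichotomy, Model 2 with the
#' ASITN/SIR dichotomy when that comparator column is present -- the two
#' collinear collateral scores are never entered together); ROC analysis of
#' the continuous angle for the favorable outcome; the collateral-by-outcome
#' contingency table with its confusion metrics; and the
#' good-collateral-by-TOAST (CE vs LAA) contingency analysis.
#'
#' @param cohort Data.frame with at least `mrs_90`, `age` and `abza_grade`
#'   (or `abza_deg`, which is then graded with `scheme`).
#' @param scheme A [grading_scheme()].
#' @param outcome_cutoff Favorable outcome is `mrs_90 <= outcome_cutoff`
#'   (default 2).
#' @param univariate_vars Variables for the univariate screen; defaults to
#'   the recognized clinical columns present in `cohort`.
#' @param model1_covariates Covariates of the ABZA model; defaults to age,
#'   TOAST, the good-collateral indicator and mTICI where present.
#' @return An object of class `abza_report` (a list of result tables).
#' @export
analyze_cohort <- function(cohort, scheme = grading_scheme(),
                           outcome_cutoff = 2L,
                           univariate_vars = NULL,
                           model1_covariates = NULL) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort: nothing to analyze", call. = FALSE)
  if (!"mrs_90" %in% names(cohort)) stop("cohort lacks an mrs_90 column", call. = FALSE)
  d <- cohort
  if (!"abza_grade" %in% names(d)) {
    if (!"abza_deg" %in% names(d)) {
      stop("cohort needs abza_grade or abza_deg", call. = FALSE)
    }
    d$abza_grade <- abza_grade(abza_trans(d$abza_deg, scheme), scheme)
  }
  d$collateral_class <- dichotomize(d$abza_grade, scheme)
  d$abza_good <- d$collateral_class == "good"
  d$favorable <- d$mrs_90 <= outcome_cutoff
  if (length(unique(d$favorable)) < 2L) {
    stop("outcome dichotomy is degenerate: only one outcome class present",
         call. = FALSE)
  }
  if ("toast" %in% names(d)) {
    d$toast <- stats::relevel(factor(d$toast), ref = "LAA")
  }
  if (is.null(univariate_vars)) {
    univariate_vars <- intersect(
      c("age", "sex", "hypertension", "diabetes", "hyperlipidemia", "chd",
        "prior_stroke", "smoking", "drinking", "nihss_baseline",
        "aspects_baseline", "toast", "onset_to_recan_min", "mtici_2b3",
        "abza_good"), names(d))
  }
  uni <- do.call(rbind, lapply(univariate_vars, function(v) {
    res <- univariate_compare(d, v, "favorable")
    data.frame(variable = v, test = res$test_name,
               statistic = ifelse(is.null(res$statistic), NA_real_, res$statistic),
               p = res$p, n_used = res$n_used, n_excluded = res$n_excluded,
               stringsAsFactors = FALSE)
  }))
  if (is.null(model1_covariates)) {
    model1_covariates <- intersect(c("age", "toast", "abza_good", "mtici_2b3"),
                                   names(d))
  }
  model1 <- fit_logistic(d, "favorable", model1_covariates, "Model 1 (ABZA)")
  model2 <- NULL
  if ("asitn_grade" %in% names(d)) {
    d$asitn_good <- d$asitn_grade > scheme$dichotomy_threshold_grade
    m2cov <- replace(model1_covariates, model1_covariates == "abza_good",
                     "asitn_good")
    model2 <- fit_logistic(d, "favorable", m2cov, "Model 2 (ASITN/SIR)")
  }
  roc <- if ("abza_deg" %in% names(d)) {
    roc_analysis(d$abza_deg, d$favorable)
  }
  tab_collat <- rbind(good = c(favorable = sum(d$abza_good & d$favorable),
                               unfavorable = sum(d$abza_good & !d$favorable)),
                      poor = c(sum(!d$abza_good & d$favorable),
                               sum(!d$abza_good & !d$favorable)))
  confusion <- confusion_metrics(tp = tab_collat["good", "favorable"],
                                 fn = tab_collat["poor", "favorable"],
                                 fp = tab_collat["good", "unfavorable"],
                                 tn = tab_collat["poor", "unfavorable"])
  outcome_by_collateral <- contingency_analysis(tab_collat)
  grade_by_toast <- NULL
  if ("toast" %in% names(d) && all(c("CE", "LAA") %in% d$toast)) {
    sub <- d[d$toast %in% c("CE", "LAA"), ]
    tab <- table(factor(sub$toast, levels = c("CE", "LAA")),
                 factor(ifelse(sub$abza_good, "good", "poor"),
                        levels = c("good", "poor")))
    grade_by_toast <- contingency_analysis(as.matrix(tab))
  }
  structure(list(n = nrow(d), outcome_cutoff = outcome_cutoff,
                 prevalence = mean(d$favorable),
                 univariate = uni, model1 = model1, model2 = model2,
                 roc = roc, collateral_by_outcome = tab_collat,
                 confusion = confusion,
                 outcome_by_collateral_test = outcome_by_collateral,
                 grade_by_toast_test = grade_by_toast,
                 scheme = scheme),
            class = "abza_report")
}

#' @export
print.abza_report <- function(x, ...) {
  cat(sprintf("<abza_report> n = %d; favorable (mRS <= %d) prevalence %.3f\n",
              x$n, x$outcome_cutoff, x$prevalence))
  cat("\nUnivariate screen:\n")
  print(transform(x$univariate, statistic = signif(statistic, 4),
                  p = signif(p, 3)), row.names = FALSE)
  cat("\n"); print(x$model1)
  if (!is.null(x$model2)) { cat("\n"); print(x$model2) }
  if (!is.null(x$roc)) { cat("\n"); print(x$roc) }
  cat("\nCollateral class vs outcome:\n"); print(x$collateral_by_outcome)
  print(x$confusion)
  cat(sprintf("  association p = %.3g (%s)\n",
              x$outcome_by_collateral_test$p,
              x$outcome_by_collateral_test$test_name))
  if (!is.null(x$grade_by_toast_test)) {
    cat(sprintf("Good collaterals by TOAST (CE vs LAA): p = %.3g (%s)\n",
                x$grade_by_toast_test$p, x$grade_by_toast_test$test_name))
  }
  invisible(x)
}

report_to_list <- function(report) {
  model_list <- function(m) {
    if (is.null(m)) return(NULL)
    list(label = m$model_label, n = m$n, coefficients = m$coefficients,
         auc = m$auc, auc_ci = m$auc_ci)
  }
  list(n = report$n, outcome_cutoff = report$outcome_cutoff,
       prevalence = report$prevalence,
       univariate = report$univariate,
       model1 = model_list(report$model1), model2 = model_list(report$model2),
       roc = if (!is.null(report$roc)) report$roc[c("auc", "auc_ci", "cutoff",
                                                    "sensitivity", "specificity",
                                                    "youden")],
       collateral_by_outcome = as.data.frame(report$collateral_by_outcome),
       confusion = report$confusion[c("sensitivity", "specificity", "youden",
                                      "odds_ratio")],
       outcome_by_collateral_test = report$outcome_by_collateral_test[
         c("test_name", "statistic", "p")],
       grade_by_toast_test = if (!is.null(report$grade_by_toast_test))
         report$grade_by_toast_test[c("test_name", "statistic", "p")])
}

#' Persist an analysis report as JSON
#'
#' @param report An [analyze_cohort()] result.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "abza_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Run the measure -> grade -> analyze pipeline with persisted outputs
#'
#' Reads landmarks (optional) and/or a cohort table, measures and grades the
#' angles, joins the scores onto the cohort, runs [analyze_cohort()], and
#' writes the per-patient score CSV plus the JSON report into `out_dir`.
#' Two runs with the same inputs and seed produce byte-identical score files
#' and numerically identical reports.
#'
#' @param cohort_file Cohort CSV (see [read_cohort()]); alternatively pass a
#'   data.frame via `cohort`.
#' @param cohort Optional in-memory cohort data.frame (overrides
#'   `cohort_file`).
#' @param landmarks_file Optional landmark CSV/JSON; measured angles replace
#'   or create the cohort's `abza_deg` column by `patient_id`.
#' @param out_dir Output directory (created if needed).
#' @param scheme A [grading_scheme()].
#' @param outcome_cutoff Favorable-outcome mRS cutoff.
#' @param seed Recorded in the report metadata (the analysis itself is
#'   deterministic).
#' @return The [analyze_cohort()] report, invisibly; side effects:
#'   `scores.csv` and `report.json` in `out_dir`.
#' @export
run_abza_pipeline <- function(cohort_file = NULL, cohort = NULL,
                              landmarks_file = NULL, out_dir,
                              scheme = grading_scheme(), outcome_cutoff = 2L,
                              seed = 1L) {
  if (is.null(cohort)) {
    if (is.null(cohort_file)) stop("supply cohort or cohort_file", call. = FALSE)
    cohort <- read_cohort(cohort_file)
  }
  if (nrow(cohort) == 0L) stop("empty cohort: aborting before analysis", call. = FALSE)
  if (!is.null(landmarks_file)) {
    lms <- read_landmarks(landmarks_file)
    meas <- measure_abza_batch(lms)
    cohort$abza_deg <- meas$abza_deg[match(cohort$patient_id, meas$patient_id)]
  }
  if ("abza_deg" %in% names(cohort)) {
    graded <- grade_angles(cohort$abza_deg, scheme)
    cohort$abza_trans <- graded$abza_trans
    cohort$abza_grade <- graded$abza_grade
    cohort$collateral_class <- graded$collateral_class
  }
  report <- analyze_cohort(cohort, scheme = scheme,
                           outcome_cutoff = outcome_cutoff)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, file.path(out_dir, "scores.csv"))
  write_report(report, file.path(out_dir, "report.json"))
  meta <- list(package_version = as.character(utils::packageVersion("abza")),
               seed = seed, outcome_cutoff = outcome_cutoff,
               norm_upper_deg = scheme$norm_upper_deg, n = nrow(cohort))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
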