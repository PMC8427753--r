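# Recomputation of the printed summary statistics of the development cohort
# from its published contingency counts.

#' Round half up to a given number of decimals
#'
#' Plain half-up rounding used when comparing recomputed percentages with
#' printed ones (banker's rounding in [round()] would turn 9/72 = 12.5 into
#' 12 rather than the printed 13).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Path to the bundled reference-cohort count fixture
#'
#' @return File path of the JSON fixture with the development cohort's
#'   printed contingency counts and summary values.
#' @export
reference_counts_path <- function() {
  system.file("extdata", "reference_cohort_counts.json", package = "abza",
              mustWork = TRUE)
}

#' Recompute the printed summary statistics from the reference counts
#'
#' Loads the bundled (or a user-supplied) JSON file of printed contingency
#' counts from the 108-patient development cohort and recomputes every
#' summary statistic that is derivable from them: diagnostic sensitivity,
#' specificity and Youden index of the good-collateral dichotomy for the
#' favorable 90-day outcome; the favorable-outcome prevalence; the
#' favorable-outcome proportions within the good- and poor-collateral
#' subgroups; the good-collateral proportions within the CE and LAA TOAST
#' subgroups; and the degree-space grade-2/3 boundary of the default grading
#' scheme. Each recomputed value is compared against the printed one at its
#' printed precision (half-up rounding).
#'
#' @param path JSON fixture path; defaults to the bundled counts.
#' @param scheme A [grading_scheme()] supplying the grade-boundary check.
#' @return A data.frame of class `abza_reproduction` with columns
#'   `quantity`, `computed` (full precision), `computed_rounded`, `reported`,
#'   `pass`.
#' @export
#' @examples
#' reproduce_printed_tables()
reproduce_printed_tables <- function(path = reference_counts_path(),
                                     scheme = grading_scheme()) {
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("cohort", "two_by_two", "outcome_by_collateral",
            "grade_gt2_by_toast", "reported")
  if (!all(need %in% names(fx))) {
    stop("fixture schema mismatch: missing section(s) ",
         paste(setdiff(need, names(fx)), collapse = ", "), call. = FALSE)
  }
  tb <- fx$two_by_two
  cm <- confusion_metrics(tp = tb$tp, fn = tb$fn, fp = tb$fp, tn = tb$tn)
  oc <- fx$outcome_by_collateral
  tg <- fx$grade_gt2_by_toast
  rep_ <- fx$reported
  rows <- list(
    list("sensitivity_pct", 100 * cm$sensitivity, 1, rep_$sensitivity_pct),
    list("specificity_pct", 100 * cm$specificity, 1, rep_$specificity_pct),
    list("youden", cm$youden, 3, rep_$youden),
    list("prevalence_pct", 100 * fx$cohort$favorable_mrs_le2 / fx$cohort$n, 1,
         rep_$prevalence_pct),
    list("mrs_le2_good_collateral_pct",
         100 * oc$good_collateral$mrs_le2 / oc$good_collateral$n, 0,
         rep_$mrs_le2_good_collateral_pct),
    list("mrs_le2_poor_collateral_pct",
         100 * oc$poor_collateral$mrs_le2 / oc$poor_collateral$n, 0,
         rep_$mrs_le2_poor_collateral_pct),
    list("grade_gt2_ce_pct", 100 * tg$CE$gt2 / tg$CE$n, 0, rep_$grade_gt2_ce_pct),
    list("grade_gt2_laa_pct", 100 * tg$LAA$gt2 / tg$LAA$n, 0,
         rep_$grade_gt2_laa_pct),
    list("grade2_to_3_boundary_deg", scheme$dashed_edges_deg[2], 1,
         rep_$grade2_to_3_boundary_deg)
  )
  out <- data.frame(
    quantity = vapply(rows, function(r) r[[1]], ""),
    computed = vapply(rows, function(r) r[[2]], 0),
    computed_rounded = vapply(rows, function(r) round_half_up(r[[2]], r[[3]]), 0),
    reported = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    stringsAsFactors = FALSE)
  out$pass <- out$computed_rounded == out$reported
  class(out) <- c("abza_reproduction", "data.frame")
  out
}

#' @export
print.abza_reproduction <- function(x, ...) {
  cat("<abza_reproduction> recomputed printed statistics\n")
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  print(df, row.names = FALSE)
  invisible(x)
}
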