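# Normalization of the measured angle against the upper normal reference
# limit and binning into the 0-4 collateral score.

#' Define an ABZA grading scheme
#'
#' The measured angle is divided by `norm_upper_deg` -- 23.0 degrees by
#' default, the upper limit of the 95% normal reference range of ABZA -- to
#' give the dimensionless `abza_trans`. Rounding `abza_trans` to the nearest
#' integer (half-integers rounding up) yields the 0-4 grade, i.e. the bins
#' are: trans <= 1 -> 0; (1, 1.5) -> 1; [1.5, 2.5) -> 2; [2.5, 3.5) -> 3;
#' [3.5, 90/norm] -> 4. In degree space (norm 23.0) the solid grade
#' boundaries sit at 23.0, 46.0, 69.0 and the dashed rounding boundaries at
#' 34.5, 57.5, 80.5 degrees. Grade > `dichotomy_threshold_grade` (default 2)
#' defines good collaterals.
#'
#' `boundary_one` resolves the overlap of the stated bins at exactly
#' trans = 1.0 (both "grade 0 if trans <= 1.0" and "grade 1 if 1 <= trans"):
#' `"grade0"` (default) treats an angle at the normal reference limit as no
#' collateral recruitment and warns; `"grade1"` rounds it up.
#'
#' @param norm_upper_deg Positive normalization constant in degrees.
#' @param dichotomy_threshold_grade Integer grade above which collaterals are
#'   classed good.
#' @param boundary_one `"grade0"` or `"grade1"`.
#' @return An object of class `grading_scheme` with derived degree-space
#'   edges `solid_edges_deg` and `dashed_edges_deg`.
#' @export
#' @examples
#' sch <- grading_scheme()
#' sch$dashed_edges_deg      # 34.5 57.5 80.5
#' abza_grade(abza_trans(45.4, sch), sch)  # 2
grading_scheme <- function(norm_upper_deg = 23.0,
                           dichotomy_threshold_grade = 2L,
                           boundary_one = c("grade0", "grade1")) {
  stopifnot(is.numeric(norm_upper_deg), length(norm_upper_deg) == 1L,
            is.finite(norm_upper_deg), norm_upper_deg > 0,
            dichotomy_threshold_grade %in% 0:4)
  boundary_one <- match.arg(boundary_one)
  structure(list(norm_upper_deg = norm_upper_deg,
                 dichotomy_threshold_grade = as.integer(dichotomy_threshold_grade),
                 boundary_one = boundary_one,
                 solid_edges_deg = norm_upper_deg * c(1, 2, 3),
                 dashed_edges_deg = norm_upper_deg * c(1.5, 2.5, 3.5),
                 max_trans = 90 / norm_upper_deg),
            class = "grading_scheme")
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat(sprintf("<grading_scheme> norm = %.1f degrees; good collaterals: grade > %d\n",
              x$norm_upper_deg, x$dichotomy_threshold_grade))
  cat(sprintf("  solid edges (deg): %s; dashed edges (deg): %s\n",
              paste(format(x$solid_edges_deg), collapse = ", "),
              paste(format(x$dashed_edges_deg), collapse = ", ")))
  invisible(x)
}

#' Normalize an angle to the dimensionless ABZA_trans ratio
#'
#' @param abza_deg Angle(s) in degrees, each in `[0, 90]`.
#' @param scheme A [grading_scheme()].
#' @return `abza_deg / norm_upper_deg`, vectorized.
#' @export
abza_trans <- function(abza_deg, scheme = grading_scheme()) {
  stopifnot(inherits(scheme, "grading_scheme"), is.numeric(abza_deg))
  if (any(!is.finite(abza_deg)) || any(abza_deg < -1e-9 | abza_deg > 90 + 1e-9)) {
    stop("abza_deg out of range: angles must lie in [0, 90] degrees", call. = FALSE)
  }
  pmin(pmax(abza_deg, 0), 90) / scheme$norm_upper_deg
}

#' Bin ABZA_trans into the 0-4 collateral grade
#'
#' Piecewise: trans <= 1 -> 0; (1, 1.5) -> 1; [1.5, 2.5) -> 2;
#' [2.5, 3.5) -> 3; [3.5, 90/norm] -> 4. Exactly 1.0 follows the scheme's
#' `boundary_one` rule (default grade 0, with a warning flagging the
#' boundary case).
#'
#' @param trans ABZA_trans ratio(s), each in `[0, 90/norm_upper_deg]`.
#' @param scheme A [grading_scheme()].
#' @return Integer grade(s) in 0..4.
#' @export
abza_grade <- function(trans, scheme = grading_scheme()) {
  stopifnot(inherits(scheme, "grading_scheme"), is.numeric(trans))
  if (any(!is.finite(trans)) ||
      any(trans < -1e-9 | trans > scheme$max_trans + 1e-9)) {
    stop(sprintf("abza_trans out of range: must lie in [0, %.4f] (angle <= 90 degrees)",
                 scheme$max_trans), call. = FALSE)
  }
  g <- integer(length(trans))
  g[trans > 1 & trans < 1.5] <- 1L
  g[trans >= 1.5 & trans < 2.5] <- 2L
  g[trans >= 2.5 & trans < 3.5] <- 3L
  g[trans >= 3.5] <- 4L
  at_one <- abs(trans - 1) < 1e-12
  if (any(at_one)) {
    if (scheme$boundary_one == "grade0") {
      g[at_one] <- 0L
      warning(sum(at_one), " value(s) at exactly ABZA_trans = 1.0 graded 0 ",
              "(angle at the normal reference limit); set boundary_one = ",
              "\"grade1\" to round up")
    } else {
      g[at_one] <- 1L
    }
  }
  g
}

#' Dichotomize a grade into good vs. poor collaterals
#'
#' Good collateral circulation is defined as grade strictly above the
#' scheme's threshold (default: grade > 2).
#'
#' @param grade Integer grade(s) in 0..4.
#' @param scheme A [grading_scheme()].
#' @return Character vector, `"good"` or `"poor"`.
#' @export
dichotomize <- function(grade, scheme = grading_scheme()) {
  stopifnot(inherits(scheme, "grading_scheme"))
  if (any(!grade %in% 0:4)) stop("grades must be integers in 0..4", call. = FALSE)
  ifelse(grade > scheme$dichotomy_threshold_grade, "good", "poor")
}

#' Grade a vector of measured angles in one call
#'
#' Convenience wrapper chaining [abza_trans()], [abza_grade()] and
#' [dichotomize()].
#'
#' @param abza_deg Angles in degrees.
#' @param scheme A [grading_scheme()].
#' @return A data.frame with columns `abza_deg`, `abza_trans`, `abza_grade`,
#'   `collateral_class`.
#' @export
grade_angles <- function(abza_deg, scheme = grading_scheme()) {
  tr <- abza_trans(abza_deg, scheme)
  g <- abza_grade(tr, scheme)
  data.frame(abza_deg = abza_deg, abza_trans = tr, abza_grade = g,
             collateral_class = dichotomize(g, scheme),
             stringsAsFactors = FALSE)
}

#' Degree-space interval covered by each grade
#'
#' Used by the synthetic-data generator (angles drawn uniformly within the
#' grade's interval) and for reporting the boundary at which the good/poor
#' dichotomy switches (2.5 x norm = 57.5 degrees under the default scheme).
#'
#' @param scheme A [grading_scheme()].
#' @return A data.frame with columns `grade`, `lower_deg`, `upper_deg`
#'   (lower edge closed for grades 2-4, open for grade 1; grade 0 covers
#'   `[0, norm]`).
#' @export
grade_intervals <- function(scheme = grading_scheme()) {
  nu <- scheme$norm_upper_deg
  data.frame(grade = 0:4,
             lower_deg = c(0, 1, 1.5, 2.5, 3.5) * nu,
             upper_deg = c(pmin(c(1, 1.5, 2.5, 3.5) * nu, 90), 90))
}
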