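# Geometric measurement of the anterior borderzone angle (ABZA) from 2D
# angiographic landmarks. All points are length-2 numeric vectors in arbitrary
# but consistent image units; orientation is carried entirely by the ordered
# (base, apex) midline pair, apex pointing toward the sagittal-sinus apex.

#' Construct a validated landmark set for one ABZA measurement
#'
#' Bundles the 2D landmarks digitized from a single anteroposterior DSA
#' projection together with the anatomical flags that select the measurement
#' rule. Points are length-2 numeric vectors in any consistent unit; no pixel
#' grid or y-axis direction is assumed.
#'
#' @param patient_id Character scalar identifying the patient (or
#'   patient-rater pair for reliability studies).
#' @param side `"left"` or `"right"`: the symptomatic carotid territory.
#' @param t_point Intracranial ICA bifurcation point T.
#' @param mid_base,mid_apex Two distinct points defining the sagittal-sinus
#'   midline, ordered base (caudal) to apex (cranial).
#' @param terminal_candidates Numeric matrix with 2 columns (one candidate per
#'   row), a single length-2 vector, or `NULL`. Candidates for the ACA--MCA
#'   pial borderzone center C; for complete MCA occlusion these are the
#'   farthest points reached by retrograde pial flow. May be empty only in
#'   the zero-angle case (no A1, no patent AcoA).
#' @param occlusion `"mcao_complete"` or `"stenosis_patent"`.
#' @param a1_status `"normal"` or `"hypoplastic_or_absent"` (ipsilateral
#'   ACA-A1 diameter below 0.5 mm or missing).
#' @param acoa_patent Logical: is the anterior communicating artery patent?
#' @param measured_from_contralateral Logical: were these landmarks taken
#'   from the contralateral carotid injection? Required when A1 is
#'   hypoplastic/absent but the AcoA is patent; forbidden when A1 is normal.
#'
#' @return An object of class `angio_landmarks`.
#' @export
#' @examples
#' lm <- angio_landmarks("p1", "left", t_point = c(3, 4),
#'                       mid_base = c(0, 0), mid_apex = c(0, 10),
#'                       terminal_candidates = c(5, 9))
#' measure_abza(lm)
angio_landmarks <- function(patient_id, side,
                            t_point, mid_base, mid_apex,
                            terminal_candidates = NULL,
                            occlusion = c("stenosis_patent", "mcao_complete"),
                            a1_status = c("normal", "hypoplastic_or_absent"),
                            acoa_patent = TRUE,
                            measured_from_contralateral = FALSE) {
  occlusion <- match.arg(occlusion)
  a1_status <- match.arg(a1_status)
  side <- match.arg(side, c("left", "right"))
  t_point <- as_point(t_point, "t_point")
  mid_base <- as_point(mid_base, "mid_base")
  mid_apex <- as_point(mid_apex, "mid_apex")
  if (sqrt(sum((mid_apex - mid_base)^2)) <= .abza_tol) {
    stop("invalid landmarks: midline base and apex coincide (degenerate midline)",
         call. = FALSE)
  }
  tc <- as_candidate_matrix(terminal_candidates)
  stopifnot(is.logical(acoa_patent), length(acoa_patent) == 1L, !is.na(acoa_patent),
            is.logical(measured_from_contralateral),
            length(measured_from_contralateral) == 1L,
            !is.na(measured_from_contralateral))
  if (a1_status == "normal" && measured_from_contralateral) {
    stop("invalid landmarks: contralateral measurement flagged but ACA-A1 is normal",
         call. = FALSE)
  }
  if (nrow(tc) == 0L && !(a1_status == "hypoplastic_or_absent" && !acoa_patent)) {
    stop("invalid landmarks: terminal candidates may be empty only when ",
         "A1 is hypoplastic/absent and the AcoA is not patent (zero-angle case)",
         call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id), side = side,
         t_point = t_point, mid_base = mid_base, mid_apex = mid_apex,
         terminal_candidates = tc, occlusion = occlusion,
         a1_status = a1_status, acoa_patent = acoa_patent,
         measured_from_contralateral = measured_from_contralateral),
    class = "angio_landmarks")
}

.abza_tol <- 1e-9

as_point <- function(p, what) {
  p <- as.numeric(p)
  if (length(p) != 2L || anyNA(p) || any(!is.finite(p))) {
    stop("invalid landmarks: ", what, " must be a finite 2D point", call. = FALSE)
  }
  p
}

as_candidate_matrix <- function(x) {
  if (is.null(x) || (is.atomic(x) && length(x) == 0L)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("x", "y"))))
  }
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 2L) x <- matrix(x, ncol = 2L)
  x <- as.matrix(x)
  if (ncol(x) != 2L || anyNA(x) || any(!is.finite(x))) {
    stop("invalid landmarks: terminal candidates must be finite 2D points",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("x", "y"))
  x
}

#' @export
print.angio_landmarks <- function(x, ...) {
  cat(sprintf("<angio_landmarks> patient %s (%s side)\n", x$patient_id, x$side))
  cat(sprintf("  T = (%.4g, %.4g); midline (%.4g, %.4g) -> (%.4g, %.4g)\n",
              x$t_point[1], x$t_point[2], x$mid_base[1], x$mid_base[2],
              x$mid_apex[1], x$mid_apex[2]))
  cat(sprintf("  %d terminal candidate(s); occlusion = %s; A1 = %s; AcoA patent = %s%s\n",
              nrow(x$terminal_candidates), x$occlusion, x$a1_status,
              x$acoa_patent,
              if (x$measured_from_contralateral) "; contralateral" else ""))
  invisible(x)
}

#' Orthogonally project the ICA bifurcation onto the sagittal midline
#'
#' Returns the vertex O: the foot of the perpendicular from T to the infinite
#' line through the (base, apex) midline pair. O satisfies
#' (O - T) . (apex - base) = 0 up to floating tolerance.
#'
#' @param t_point 2D point T (ICA bifurcation).
#' @param mid_base,mid_apex The ordered midline pair.
#' @return Length-2 numeric vector O.
#' @export
#' @examples
#' project_vertex(c(3, 4), c(0, 0), c(0, 10))  # (0, 4)
project_vertex <- function(t_point, mid_base, mid_apex) {
  t_point <- as_point(t_point, "t_point")
  mid_base <- as_point(mid_base, "mid_base")
  mid_apex <- as_point(mid_apex, "mid_apex")
  d <- mid_apex - mid_base
  dd <- sum(d * d)
  if (sqrt(dd) <= .abza_tol) {
    stop("invalid landmarks: midline base and apex coincide (degenerate midline)",
         call. = FALSE)
  }
  mid_base + (sum((t_point - mid_base) * d) / dd) * d
}

#' Reduce terminal-point candidates to a single borderzone center
#'
#' A single candidate is returned unchanged; several candidates (the farthest
#' points of retrograde pial flow in complete MCA occlusion) are reduced to
#' their centroid. Raters who prefer a different central point can supply it
#' as the single candidate.
#'
#' @param candidates Matrix with 2 columns, one candidate per row (or a
#'   single length-2 vector).
#' @return Length-2 numeric vector C.
#' @export
resolve_terminal_point <- function(candidates) {
  m <- as_candidate_matrix(candidates)
  if (nrow(m) == 0L) {
    stop("no terminal candidates: route this case to the zero-angle rule",
         call. = FALSE)
  }
  colMeans(m)
}

#' Unsigned angle between the midline apex direction and the ray O -> C
#'
#' The starting edge is the midline (in its apex direction), the ending edge
#' is the ray from the vertex O to the terminal point C. The angle is
#' unsigned and laterality-agnostic: mirror-image terminal points yield the
#' same value. Values in (90, 90.5] degrees are clamped to 90 with a warning
#' (marker jitter); larger values signal a terminal point below the vertex,
#' most often a swapped midline base/apex, and raise an error.
#'
#' @param vertex_o 2D vertex O (see [project_vertex()]).
#' @param terminal_c 2D terminal point C, distinct from O.
#' @param mid_base,mid_apex The ordered midline pair.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
angle_from_midline <- function(vertex_o, terminal_c, mid_base, mid_apex) {
  o <- as_point(vertex_o, "vertex_o")
  cpt <- as_point(terminal_c, "terminal_c")
  mid_base <- as_point(mid_base, "mid_base")
  mid_apex <- as_point(mid_apex, "mid_apex")
  u <- mid_apex - mid_base
  if (sqrt(sum(u * u)) <= .abza_tol) {
    stop("invalid landmarks: midline base and apex coincide (degenerate midline)",
         call. = FALSE)
  }
  v <- cpt - o
  nv <- sqrt(sum(v * v))
  if (nv <= .abza_tol) {
    stop("undefined angle: terminal point coincides with the vertex", call. = FALSE)
  }
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * nv)
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  if (ang > 90 + 0.5) {
    stop(sprintf(paste0("angle %.2f degrees out of range: the terminal point lies ",
                        "below the vertex (midline base/apex likely swapped)"), ang),
         call. = FALSE)
  }
  if (ang > 90) {
    warning(sprintf("angle %.4f degrees clamped to 90 (measurement jitter)", ang))
    ang <- 90
  }
  ang
}

#' Measure the anterior borderzone angle for one patient
#'
#' Applies the full measurement protocol: when the ipsilateral ACA-A1 is
#' hypoplastic/absent and the AcoA is closed, the collateral supply cannot be
#' visualized and ABZA is 0 degrees by definition; when A1 is absent but the
#' AcoA is patent, landmarks must come from the contralateral carotid
#' injection (the caller sets `measured_from_contralateral`); otherwise the
#' vertex O is the orthogonal projection of T on the midline and the angle is
#' measured from the midline to the ray O -> C, with C the (centroid of the)
#' terminal candidate(s) -- the farthest retrograde pial points under complete
#' MCA occlusion, the first-meeting point of ACA and MCA pial arterioles
#' otherwise.
#'
#' @param landmarks An [angio_landmarks()] object.
#' @return An object of class `abza_measurement` with fields `abza_deg`
#'   (degrees, in `[0, 90]`), `vertex_o`, `terminal_c` (`NULL` in the
#'   zero-angle case), `rule_applied` (one of `"standard"`,
#'   `"mcao_retrograde"`, `"contralateral"`, `"zero_no_a1_no_acoa"`) and
#'   `patient_id`.
#' @export
measure_abza <- function(landmarks) {
  stopifnot(inherits(landmarks, "angio_landmarks"))
  lm <- landmarks
  if (lm$a1_status == "hypoplastic_or_absent" && !lm$acoa_patent) {
    return(new_abza_measurement(lm$patient_id, 0, vertex_o = NULL,
                                terminal_c = NULL,
                                rule = "zero_no_a1_no_acoa"))
  }
  if (lm$a1_status == "hypoplastic_or_absent" && lm$acoa_patent &&
      !lm$measured_from_contralateral) {
    stop("protocol violation: with a hypoplastic/absent A1 and a patent AcoA, ",
         "ABZA must be measured from contralateral carotid angiography images ",
         "(set measured_from_contralateral = TRUE and supply those landmarks)",
         call. = FALSE)
  }
  rule <- if (lm$measured_from_contralateral) {
    "contralateral"
  } else if (lm$occlusion == "mcao_complete") {
    "mcao_retrograde"
  } else {
    "standard"
  }
  o <- project_vertex(lm$t_point, lm$mid_base, lm$mid_apex)
  cpt <- resolve_terminal_point(lm$terminal_candidates)
  deg <- angle_from_midline(o, cpt, lm$mid_base, lm$mid_apex)
  new_abza_measurement(lm$patient_id, deg, vertex_o = o, terminal_c = cpt,
                       rule = rule)
}

new_abza_measurement <- function(patient_id, deg, vertex_o, terminal_c, rule) {
  structure(list(patient_id = patient_id, abza_deg = deg,
                 vertex_o = vertex_o, terminal_c = terminal_c,
                 rule_applied = rule),
            class = "abza_measurement")
}

#' @export
print.abza_measurement <- function(x, ...) {
  cat(sprintf("<abza_measurement> patient %s: ABZA = %.3f degrees (rule: %s)\n",
              x$patient_id, x$abza_deg, x$rule_applied))
  invisible(x)
}

#' Measure ABZA for a list of landmark sets
#'
#' @param landmark_list List of [angio_landmarks()] objects, e.g. from
#'   [read_landmarks()].
#' @return A data.frame with columns `patient_id`, `abza_deg`, `rule_applied`.
#' @export
measure_abza_batch <- function(landmark_list) {
  stopifnot(is.list(landmark_list))
  res <- lapply(landmark_list, measure_abza)
  data.frame(patient_id = vapply(res, `[[`, "", "patient_id"),
             abza_deg = vapply(res, `[[`, 0, "abza_deg"),
             rule_applied = vapply(res, `[[`, "", "rule_applied"),
             stringsAsFactors = FALSE)
}
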