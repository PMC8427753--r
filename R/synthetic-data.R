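# Synthetic data: (a) landmark phantoms with known ground-truth angle for
# validating the geometry, (b) synthetic EVT cohorts with the development
# cohort's covariate structure, grade-by-TOAST distribution, outcome
# prevalence and logistic effect sizes.

#' Specify a landmark phantom with known ground-truth angle
#'
#' A phantom is built in canonical pose -- vertex at `vertex`, midline along
#' the direction `midline_angle_deg` (degrees counterclockwise from +x; the
#' apex lies in that direction), terminal point(s) at distance `radius` from
#' the vertex at the true angle -- then rotated by `rotation_deg` about the
#' origin, translated by `translation`, and optionally jittered (iid Gaussian
#' noise on T and the terminal candidates). Several candidates are fanned
#' symmetrically (half-width `fan_deg`) about the true direction so that
#' their centroid preserves the ground-truth angle exactly.
#'
#' @param true_abza_deg Ground-truth angle in `[0, 90]` degrees.
#' @param vertex Canonical vertex position (length-2).
#' @param midline_angle_deg Canonical midline (apex) direction in degrees.
#' @param radius Distance from vertex to each terminal candidate (> 0).
#' @param t_offset Signed perpendicular offset of the ICA bifurcation T from
#'   the midline (its projection is the vertex).
#' @param rotation_deg,translation Rigid transform applied to all points.
#' @param jitter_sd Standard deviation of coordinate noise on T and the
#'   terminal candidates (0 = exact landmarks).
#' @param n_candidates Number of terminal candidates (>= 1).
#' @param fan_deg Half-width of the symmetric candidate fan, degrees.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_abza_deg, vertex = c(0, 0),
                         midline_angle_deg = 90, radius = 10,
                         t_offset = 5, rotation_deg = 0,
                         translation = c(0, 0), jitter_sd = 0,
                         n_candidates = 1L, fan_deg = 0) {
  stopifnot(is.numeric(true_abza_deg), length(true_abza_deg) == 1L,
            true_abza_deg >= 0, true_abza_deg <= 90,
            radius > 0, jitter_sd >= 0, n_candidates >= 1L, fan_deg >= 0)
  structure(list(true_abza_deg = true_abza_deg,
                 vertex = as_point(vertex, "vertex"),
                 midline_angle_deg = midline_angle_deg, radius = radius,
                 t_offset = t_offset, rotation_deg = rotation_deg,
                 translation = as_point(translation, "translation"),
                 jitter_sd = jitter_sd,
                 n_candidates = as.integer(n_candidates), fan_deg = fan_deg),
            class = "phantom_spec")
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Generate a landmark set from a phantom specification
#'
#' Constructs the midline pair, the ICA bifurcation T (whose orthogonal
#' projection is the phantom vertex) and the terminal candidate(s) at the
#' ground-truth angle, applies the rigid transform, and adds jitter if
#' requested. The ground truth is retained in attributes
#' `true_abza_deg` and `true_vertex`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed for the jitter noise.
#' @param patient_id Identifier carried into the landmark set.
#' @return An [angio_landmarks()] object (occlusion is flagged
#'   `mcao_complete` when the spec has several retrograde candidates).
#' @export
generate_landmarks <- function(spec, seed = NULL, patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  u <- c(cos(spec$midline_angle_deg * pi / 180),
         sin(spec$midline_angle_deg * pi / 180))     # apex direction
  nperp <- c(-u[2], u[1])                            # left-hand normal
  o <- spec$vertex
  base <- o - 10 * u
  apex <- o + 10 * u
  t_point <- o + spec$t_offset * nperp
  th <- spec$true_abza_deg * pi / 180
  offs <- if (spec$n_candidates == 1L) 0 else
    seq(-spec$fan_deg, spec$fan_deg, length.out = spec$n_candidates) * pi / 180
  cand <- t(vapply(offs, function(d) {
    o + spec$radius * (cos(th + d) * u + sin(th + d) * nperp)
  }, numeric(2)))
  R <- rot2(spec$rotation_deg)
  tf <- function(p) as.numeric(R %*% p) + spec$translation
  base <- tf(base); apex <- tf(apex); t_point <- tf(t_point); o_tf <- tf(o)
  cand <- t(apply(cand, 1L, tf))
  if (spec$jitter_sd > 0) {
    t_point <- t_point + stats::rnorm(2L, 0, spec$jitter_sd)
    cand <- cand + matrix(stats::rnorm(length(cand), 0, spec$jitter_sd),
                          nrow = nrow(cand))
  }
  lm <- angio_landmarks(patient_id = patient_id, side = "left",
                        t_point = t_point, mid_base = base, mid_apex = apex,
                        terminal_candidates = cand,
                        occlusion = if (spec$n_candidates > 1L)
                          "mcao_complete" else "stenosis_patent")
  attr(lm, "true_abza_deg") <- spec$true_abza_deg
  attr(lm, "true_vertex") <- o_tf
  lm
}

#' Configure the synthetic EVT cohort generator
#'
#' The defaults reproduce the structure of the 108-patient development
#' cohort: TOAST mix 44 LAA / 59 CE / 5 other, good-collateral probability
#' 23/44 in LAA, 10/59 in CE and 3/5 in the residual class (the split implied
#' by the 36/108 overall margin), grade distribution within each dichotomy
#' arm taken from the printed grade margins (4:30:38 over grades 0-2,
#' 31:5 over grades 3-4), age approximately Normal(68, 9) truncated to
#' [30, 95] years, and a logistic outcome model for favorable 90-day mRS
#' with per-year age odds ratio 0.939 and good-collateral odds ratio 18.948,
#' intercept calibrated to a marginal favorable prevalence of 0.343.
#'
#' Covariates are drawn independently; the marginals are illustrative
#' conventions, not estimates of the study population.
#'
#' @param n Number of patients.
#' @param age_mean,age_sd,age_bounds Truncated-normal age model (years).
#' @param male_p,mtici_p,risk_prevalences Bernoulli prevalences (the risk
#'   list is named: hypertension, diabetes, hyperlipidemia, chd,
#'   prior_stroke, smoking, drinking).
#' @param toast_p Named probabilities over `LAA`, `CE`, `other` (sum 1).
#' @param p_good_by_toast Named P(grade > 2 | TOAST).
#' @param grade_within_poor Probabilities over grades 0,1,2 given grade <= 2.
#' @param grade_within_good Probabilities over grades 3,4 given grade > 2.
#' @param beta_age Log odds of favorable outcome per year of age.
#' @param beta_goodcollat Log odds for the good-collateral indicator.
#' @param beta_mtici Log odds for successful recanalization (default 0: in
#'   the development cohort mTICI was not an independent predictor of the
#'   favorable outcome in the ABZA model).
#' @param target_prevalence Marginal P(mRS <= 2) the intercept is calibrated
#'   to.
#' @param beta0 Optional pre-calibrated intercept; `NULL` means calibrate on
#'   first use (see [calibrate_intercept()]).
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 108,
                              age_mean = 68, age_sd = 9, age_bounds = c(30, 95),
                              male_p = 63 / 108,
                              mtici_p = 89 / 108,
                              risk_prevalences = list(
                                hypertension = 74 / 108, diabetes = 29 / 108,
                                hyperlipidemia = 26 / 108, chd = 13 / 108,
                                prior_stroke = 20 / 108, smoking = 21 / 108,
                                drinking = 13 / 108),
                              toast_p = c(LAA = 44, CE = 59, other = 5) / 108,
                              p_good_by_toast = c(LAA = 23 / 44, CE = 10 / 59,
                                                  other = 3 / 5),
                              grade_within_poor = c(4, 30, 38) / 72,
                              grade_within_good = c(31, 5) / 36,
                              beta_age = log(0.939),
                              beta_goodcollat = log(18.948),
                              beta_mtici = 0,
                              target_prevalence = 37 / 108,
                              beta0 = NULL) {
  stopifnot(n > 0, age_sd > 0, age_bounds[1] < age_bounds[2],
            male_p >= 0, male_p <= 1, mtici_p >= 0, mtici_p <= 1,
            target_prevalence > 0, target_prevalence < 1)
  check_prob_vec <- function(p, what, sum1 = TRUE) {
    if (any(p < 0) || any(p > 1)) stop(what, " must lie in [0, 1]", call. = FALSE)
    if (sum1 && abs(sum(p) - 1) > 1e-8) stop(what, " must sum to 1", call. = FALSE)
  }
  check_prob_vec(toast_p, "toast_p")
  check_prob_vec(grade_within_poor, "grade_within_poor")
  check_prob_vec(grade_within_good, "grade_within_good")
  check_prob_vec(p_good_by_toast, "p_good_by_toast", sum1 = FALSE)
  check_prob_vec(unlist(risk_prevalences), "risk_prevalences", sum1 = FALSE)
  stopifnot(identical(names(toast_p), c("LAA", "CE", "other")),
            identical(names(p_good_by_toast), c("LAA", "CE", "other")))
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 age_bounds = age_bounds, male_p = male_p, mtici_p = mtici_p,
                 risk_prevalences = risk_prevalences, toast_p = toast_p,
                 p_good_by_toast = p_good_by_toast,
                 grade_within_poor = grade_within_poor,
                 grade_within_good = grade_within_good,
                 beta_age = beta_age, beta_goodcollat = beta_goodcollat,
                 beta_mtici = beta_mtici,
                 target_prevalence = target_prevalence, beta0 = beta0),
            class = "cohort_sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Draw the covariates that enter the outcome model (age, good-collateral
# indicator, mTICI) for a sample of size n; shared by the intercept
# calibration and the cohort generator so both use the same marginals.
draw_outcome_covariates <- function(config, n) {
  age <- rtrunc_norm(n, config$age_mean, config$age_sd,
                     config$age_bounds[1], config$age_bounds[2])
  toast <- sample(names(config$toast_p), n, replace = TRUE,
                  prob = config$toast_p)
  good <- stats::rbinom(n, 1L, config$p_good_by_toast[toast])
  mtici <- stats::rbinom(n, 1L, config$mtici_p)
  list(age = age, toast = toast, good = good, mtici = mtici)
}

linear_predictor <- function(config, beta0, cov) {
  beta0 + config$beta_age * cov$age + config$beta_goodcollat * cov$good +
    config$beta_mtici * cov$mtici
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Bisection on the intercept until the mean simulated favorable-outcome
#' probability over a large covariate sample (fixed internal seed, so the
#' result is a deterministic function of the configuration) is within `tol`
#' of `target_prevalence`. With all slope coefficients zero the closed form
#' `qlogis(target)` is returned directly.
#'
#' @param config A [cohort_sim_config()].
#' @param n_calib Covariate sample size used for calibration.
#' @param tol Absolute tolerance on the achieved prevalence.
#' @param calib_seed Internal seed for the calibration sample.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, n_calib = 1e5, tol = 1e-3,
                                calib_seed = 20451L) {
  stopifnot(inherits(config, "cohort_sim_config"))
  target <- config$target_prevalence
  if (config$beta_age == 0 && config$beta_goodcollat == 0 &&
      config$beta_mtici == 0) {
    return(stats::qlogis(target))
  }
  cov <- local_seed(calib_seed, draw_outcome_covariates(config, n_calib))
  prev <- function(b0) mean(stats::plogis(linear_predictor(config, b0, cov)))
  lo <- -50; hi <- 50
  if (prev(lo) > target || prev(hi) < target) {
    stop("target prevalence unreachable given the slope coefficients",
         call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (prev(mid) < target) lo <- mid else hi <- mid
    if (abs(prev(mid) - target) <= tol && (hi - lo) < 1e-8) break
  }
  mid <- (lo + hi) / 2
  if (abs(prev(mid) - target) > tol) {
    stop("intercept calibration did not reach the target prevalence within ",
         tol, call. = FALSE)
  }
  mid
}

# Run expr under a temporary RNG state, restoring the caller's stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic EVT cohort
#'
#' Draws covariates independently per the configured marginals, the
#' collateral grade conditionally on TOAST subtype (dichotomy first, then the
#' within-arm grade split), a measured angle uniformly within the grade's
#' degree interval, the ASITN/SIR comparator as the ABZA grade perturbed by
#' at most one level (the two scales track each other approximately
#' linearly), and the favorable 90-day outcome from the logistic model.
#' Identical seeds give bitwise-identical cohorts.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Integer seed (single PRNG stream; recorded in the attributes).
#' @param scheme The [grading_scheme()] defining the grade-to-angle
#'   intervals.
#' @return A data.frame of one row per patient with demographic, risk,
#'   stroke-severity, EVT, score and outcome columns; attributes
#'   `seed`, `beta0`, `generating_coefficients`, `achieved_prevalence`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_sim_config(n = 200), seed = 1)
#' mean(coh$mrs_90 <= 2)
generate_cohort <- function(config = cohort_sim_config(), seed = 1L,
                            scheme = grading_scheme()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  beta0 <- config$beta0
  if (is.null(beta0)) beta0 <- calibrate_intercept(config)
  n <- config$n
  set.seed(seed)
  cov <- draw_outcome_covariates(config, n)
  grade <- integer(n)
  grade[cov$good == 1L] <- sample(3:4, sum(cov$good), replace = TRUE,
                                  prob = config$grade_within_good)
  grade[cov$good == 0L] <- sample(0:2, sum(cov$good == 0L), replace = TRUE,
                                  prob = config$grade_within_poor)
  iv <- grade_intervals(scheme)
  abza_deg <- stats::runif(n, iv$lower_deg[grade + 1L], iv$upper_deg[grade + 1L])
  # grade 0 includes the zero-angle (no A1, no AcoA) patients; keep angles
  # within the bin but away from the exact trans = 1 boundary
  abza_deg <- pmin(abza_deg, 90)
  asitn <- pmin(pmax(grade + sample(-1:1, n, replace = TRUE,
                                    prob = c(0.2, 0.6, 0.2)), 0L), 4L)
  p_fav <- stats::plogis(linear_predictor(config, beta0, cov))
  fav <- stats::rbinom(n, 1L, p_fav)
  mrs <- ifelse(fav == 1L, sample(0:2, n, replace = TRUE, prob = c(.3, .4, .3)),
                sample(3:6, n, replace = TRUE, prob = c(.3, .3, .2, .2)))
  rp <- config$risk_prevalences
  risks <- lapply(rp, function(p) stats::rbinom(n, 1L, p) == 1L)
  coh <- data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    age = cov$age,
    sex = ifelse(stats::rbinom(n, 1L, config$male_p) == 1L, "male", "female"),
    hypertension = risks$hypertension, diabetes = risks$diabetes,
    hyperlipidemia = risks$hyperlipidemia, chd = risks$chd,
    prior_stroke = risks$prior_stroke, smoking = risks$smoking,
    drinking = risks$drinking,
    nihss_baseline = pmin(pmax(round(stats::rnorm(n, 16.6, 5.6)), 0L), 42L),
    aspects_baseline = sample(7:10, n, replace = TRUE, prob = c(.1, .2, .3, .4)),
    toast = cov$toast,
    onset_to_recan_min = round(rtrunc_norm(n, 333, 107, 60, 900)),
    mtici_2b3 = cov$mtici == 1L,
    abza_deg = abza_deg,
    abza_grade = grade,
    asitn_grade = asitn,
    mrs_90 = as.integer(mrs),
    stringsAsFactors = FALSE)
  attr(coh, "seed") <- seed
  attr(coh, "beta0") <- beta0
  attr(coh, "generating_coefficients") <- c(
    beta0 = beta0, beta_age = config$beta_age,
    beta_goodcollat = config$beta_goodcollat, beta_mtici = config$beta_mtici)
  attr(coh, "achieved_prevalence") <- mean(fav)
  coh
}
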