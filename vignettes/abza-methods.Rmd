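---
title: "The anterior borderzone angle: measurement model, grading and prognostic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anterior borderzone angle: measurement model, grading and prognostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abza)
```

## The measurement model

Leptomeningeal collaterals supply the occluded middle cerebral artery (MCA)
territory retrogradely from the anterior cerebral artery (ACA). On an
anteroposterior DSA frame, how far laterally and inferiorly that retrograde
supply reaches is captured by a single angle. A rater places:

- **T**, the intracranial internal-carotid bifurcation;
- two points on the **sagittal-sinus midline**, ordered base → apex;
- one or more **terminal candidates**: where the pial arterioles of ACA and
  MCA first meet, or — under complete MCA occlusion — the farthest points
  reached by retrograde pial flow.

The vertex **O** is the orthogonal projection of T on the midline; the
anterior borderzone angle α is the unsigned angle between the midline's apex
direction and the ray O→C, with **C** the (centroid of the) terminal
candidate(s). α lives in [0°, 90°]: 0° means no visible retrograde supply,
90° means collateral filling all the way down to the level of the carotid
bifurcation.

Assumptions worth making explicit:

- **The 2D projection is authoritative.** Landmarks come from a standard
  anteroposterior projection; no correction for projection obliquity is
  attempted. Coordinates are continuous, in any consistent unit, with no
  assumed y-axis direction — orientation is carried entirely by the ordered
  (base, apex) midline pair. This removes every display-convention ambiguity
  a PACS viewer could introduce.
- **Angles are unsigned and laterality-agnostic**: left- and right-sided
  occlusions grade on one scale, and mirroring all landmarks across the
  midline cannot change the result (a tested invariant, alongside rigid-motion
  and scale invariance).
- **Several terminal candidates reduce to their centroid.** The protocol
  speaks of "the several farthest points" without a reduction rule; the
  centroid is the symmetric choice, and a rater who prefers a specific
  central point can supply it as the single candidate.
- **Degenerate anatomy rules.** With a hypoplastic/absent ipsilateral ACA-A1
  and a closed anterior communicating artery there is nothing to measure:
  α = 0° by definition (`rule_applied = "zero_no_a1_no_acoa"`). With an
  absent A1 but patent AcoA the measurement must come from the contralateral
  injection; the caller supplies those landmarks and sets the flag, and the
  package applies no mirroring of its own — refusing instead with a protocol
  error if the flag is missing.
- **Clamping.** α > 90° is anatomically impossible (C anterior to O);
  values in (90°, 90.5°] are treated as marker jitter and clamped to 90°
  with a warning, larger values raise an error suggesting a swapped midline
  base/apex.

## Normalization and grading

The angle is normalized by the upper limit of the 95% normal reference
range, 23.0° by default (`grading_scheme(norm_upper_deg = )`; the constant
comes from prior normative work and is deliberately configurable, not
re-derived here):

$$\mathrm{ABZA}_\mathrm{trans} = \alpha / 23.0^\circ \in [0, 3.913]$$

Rounding to the nearest integer (half-integers up) gives the 0–4 grade, so
the solid degree-space boundaries sit at 23.0°, 46.0°, 69.0° and the
effective (dashed) grade boundaries at 34.5°, 57.5°, 80.5°. Grade > 2,
i.e. α ≥ 57.5°, defines good collaterals.

Two boundary conventions needed a decision:

- **Exactly trans = 1.0** is claimed by both the grade-0 clause
  ("0 if trans ≤ 1.0") and the grade-1 bin ("1 if 1 ≤ trans < 1.5"). The
  explicit grade-0 clause wins by default — an angle still within the normal
  reference range signals no collateral recruitment — with a warning, and
  `grading_scheme(boundary_one = "grade1")` flips it. How the original
  raters scored exact boundaries is unknowable, hence the switch.
- **Sub-normal rounding**: naive rounding would send trans ∈ [0.5, 1.0] to
  grade 1; the stated piecewise bins send it to 0. The piecewise list is the
  only complete specification and is authoritative; "rounding" is a
  description, not the rule.

Grades are integers only; nothing is interpolated.

## The prognostic pipeline

`analyze_cohort()` reproduces the development study's analysis on any cohort
table with 90-day mRS and the score columns:

- **Univariate screen** (`univariate_compare()`): continuous variables are
  Shapiro–Wilk screened (0.05, per group) and routed to a pooled-variance
  t-test or Mann–Whitney U; categoricals get Pearson chi-square without
  continuity correction, switching to Fisher's exact for 2×2 tables with any
  expected count < 5. The original analysis does not name its per-variable
  tests; this routing is our convention and the chosen test is logged per
  variable. No multiplicity correction is applied (none was in the original);
  all p-values are two-sided.
- **Logistic models** (`fit_logistic()`): maximum-likelihood fits entering
  all covariates simultaneously ("enter" method). The two collateral scores
  (ABZA-grading and the ASITN/SIR comparator) track each other approximately
  linearly, so they are never entered together: Model 1 keeps the ABZA
  dichotomy, Model 2 the ASITN/SIR dichotomy. Odds-ratio confidence
  intervals and p-values are Wald (matching the SPSS defaults the original
  analysis used); TOAST enters as a three-level factor with LAA as
  reference. Complete/quasi-separation (diverging coefficients) and
  non-convergence raise explicit errors rather than returning meaningless
  Wald statistics.
- **ROC** (`roc_analysis()`): the empirical curve is scanned at midpoints
  between sorted unique scores, predicting the favorable state when
  score > cutoff; AUC is the trapezoid area (identical to the
  concordance probability with ties counted ½ — a tested identity), the AUC
  interval is DeLong's (via pROC), and the optimal cutoff maximizes the
  Youden index with exact ties broken toward higher specificity. The
  midpoint convention is consistent with the development cohort's reported
  empirical optimum (57.8°) sitting just above the 57.5° grade boundary.
- **Contingency analyses** (`contingency_analysis()`): Pearson chi-square on
  the r×c table (Fisher fallback as above) for mRS-by-collateral-class and
  grading-by-TOAST.
- **Inter-rater reliability** (`interrater_reliability()`): the development
  study reports a single unnamed "IRR" coefficient, so both defensible
  readings are implemented — ICC(A,1) (two-way, absolute agreement, single
  measures) for continuous angles and linearly weighted Cohen's kappa for
  ordinal grades — and the caller picks the mode.
- **Missing data**: complete-case per analysis, with exclusion counts
  reported. The favorable-outcome dichotomy is mRS ≤ 2, configurable via
  `outcome_cutoff`.

## The synthetic-data generator

Patient-level data of the development cohort are not deposited, so
validation runs on synthetic data with known ground truth.

**Phantoms** (`phantom_spec()` / `generate_landmarks()`) build landmark sets
in canonical pose at an exact ground-truth angle, then apply a rigid
transform and optional Gaussian landmark jitter. Multiple candidates are
fanned symmetrically about the true direction so their centroid preserves
the angle exactly. Tested properties: round-trip recovery to 1e−6 degrees
over an angle grid under random rigid motion, mirror and scale invariance,
and unbiasedness of the measured angle under symmetric jitter.

**Cohorts** (`cohort_sim_config()` / `generate_cohort()`) draw covariates
independently and pass them through a logistic outcome model. The defaults
are the development cohort's structure, fixed once: n = 108; TOAST mix
44 LAA / 59 CE / 5 other; P(grade > 2 | TOAST) = 23/44, 10/59 and 3/5 (the
residual class's value is implied by the overall 36/108 good-collateral
margin); within-arm grade splits 4:30:38 (grades 0–2) and 31:5 (grades 3–4)
from the printed grade margins; age ~ Normal(68, 9) truncated to [30, 95]
years, approximating the printed medians; angles uniform within the grade's
degree interval (no within-grade distribution is reported); and outcome
coefficients β_age = ln(0.939) per year, β_goodcollat = ln(18.948), with the
intercept calibrated by bisection (`calibrate_intercept()`, fixed internal
seed, tolerance 1e−3) to the 34.3% favorable prevalence. mTICI enters the
generator with coefficient 0 by default: it was not an independent predictor
in the ABZA model. Each cohort uses a single seeded PRNG stream; identical
seeds give bitwise-identical tables.

What the generator deliberately does **not** emulate: covariate
correlations (none are reported; everything is drawn independently),
measurement disagreement between raters, within-grade angle clustering, and
any real DSA imaging artifacts. Passing the parameter-recovery and
distributional tests therefore shows the pipeline is statistically correct
and internally consistent — not that the effect sizes would replicate in a
new clinical cohort.

## Numerical conventions and problem sizes

- Degenerate midlines (coincident points) are rejected at tolerance 1e−9;
  angle round-trip accuracy is tested at 1e−6 degrees.
- The Youden identity (sens + spec − 1) and the AUC–concordance identity are
  asserted to 1e−12.
- CSV output is full precision, comma-separated, UTF-8, "." decimal; display
  rounding appears only in human-readable tables. Percentages compared with
  printed values use half-up rounding (`round_half_up()`), since banker's
  rounding would turn 9/72 = 12.5% into 12 rather than the printed 13.
- The parameter-recovery experiment uses 200 replicates of n = 2000 — large
  enough that the median fitted odds ratios sit within a few percent of the
  generating values (the small-sample bias of the logistic MLE is away from
  the null, hence a slight upward drift of the good-collateral OR), small
  enough to run in well under a minute per 200 fits on one core.
  Distributional checks (prevalence, grade-by-TOAST) use n = 1e5 draws
  against 3–3.5 Monte-Carlo standard errors.

## Known limitations

- The headline clinical AUC (0.868) and the empirical 57.8° cutoff of the
  development cohort are not reproducible without its patient-level data;
  the package instead verifies the cutoff *convention* (midpoints above the
  57.5° boundary) and the AUC's structural identities.
- The 23.0° normalization constant is taken as given, not re-derived.
- The ASITN/SIR comparator is accepted as an externally supplied column;
  no mapping between the two scales is attempted beyond the shared
  dichotomy.
- DeLong intervals can differ slightly from SPSS's nonparametric AUC
  intervals (asymptotically equivalent, not identical); Wald intervals for
  ORs are anti-conservative near separation, which the fit refuses outright.
- Which statistic the reported IRR of 0.78 denotes is unknown; both ICC and
  weighted kappa are provided rather than guessing silently.
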