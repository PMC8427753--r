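test_that("project_vertex matches axis-aligned and closed-form cases", {
  expect_equal(project_vertex(c(3, 4), c(0, 0), c(0, 10)), c(0, 4))
  expect_equal(project_vertex(c(0, 7), c(0, 0), c(0, 10)), c(0, 7))
  # diagonal midline: checked against a dense grid search minimizing distance
  o <- project_vertex(c(2, 0), c(0, 0), c(10, 10))
  expect_equal(o, c(1, 1))
  expect_equal(o, grid_project(c(2, 0), c(0, 0), c(10, 10)), tolerance = 1e-3)
})

test_that("project_vertex minimizes distance to the midline on random instances", {
  set.seed(11)
  for (i in 1:10) {
    base <- runif(2, -5, 5); apex <- base + runif(2, 0.5, 5)
    tp <- runif(2, -5, 5)
    o <- project_vertex(tp, base, apex)
    expect_equal(sum((o - tp) * (apex - base)), 0, tolerance = 1e-9)
    g <- grid_project(tp, base, apex)
    expect_lte(sqrt(sum((o - tp)^2)), sqrt(sum((g - tp)^2)) + 1e-6)
  }
})

test_that("degenerate midline is rejected everywhere", {
  expect_error(project_vertex(c(1, 1), c(2, 2), c(2, 2)), "degenerate midline")
  expect_error(angio_landmarks("p", "left", c(1, 1), c(2, 2), c(2, 2),
                               terminal_candidates = c(0, 0)),
               "degenerate midline")
})

test_that("resolve_terminal_point returns singleton or centroid", {
  expect_equal(resolve_terminal_point(c(4, 2)), c(x = 4, y = 2))
  expect_equal(resolve_terminal_point(rbind(c(4, 2), c(6, 4))), c(x = 5, y = 3))
  expect_equal(resolve_terminal_point(rbind(c(0, 0), c(3, 0), c(0, 3))),
               c(x = 1, y = 1))
  expect_error(resolve_terminal_point(NULL), "zero-angle")
})

test_that("angle_from_midline covers the cardinal and mirror cases", {
  b <- c(0, -10); a <- c(0, 10)
  expect_equal(angle_from_midline(c(0, 0), c(5, 5), b, a), 45)
  expect_equal(angle_from_midline(c(0, 0), c(0, 7), b, a), 0)
  expect_equal(angle_from_midline(c(0, 0), c(-5, 5), b, a), 45)
  expect_equal(angle_from_midline(c(0, 0), c(7, 0), b, a), 90)
})

test_that("angle_from_midline clamps small overshoots and rejects large ones", {
  b <- c(0, -10); a <- c(0, 10)
  th <- 90.3 * pi / 180  # just below the vertex
  expect_warning(ang <- angle_from_midline(c(0, 0), 5 * c(sin(th), cos(th)), b, a),
                 "clamped")
  expect_equal(ang, 90)
  th2 <- 120 * pi / 180
  expect_error(angle_from_midline(c(0, 0), 5 * c(sin(th2), cos(th2)), b, a),
               "below the vertex")
  expect_error(angle_from_midline(c(0, 0), c(0, 0), b, a), "coincides")
})

test_that("measure_abza applies the zero-angle and contralateral rules", {
  zero <- angio_landmarks("z", "left", c(3, 4), c(0, 0), c(0, 10),
                          terminal_candidates = NULL,
                          a1_status = "hypoplastic_or_absent",
                          acoa_patent = FALSE)
  m <- measure_abza(zero)
  expect_equal(m$abza_deg, 0)
  expect_identical(m$rule_applied, "zero_no_a1_no_acoa")
  expect_null(m$terminal_c)

  expect_error(
    measure_abza(angio_landmarks("v", "left", c(3, 4), c(0, 0), c(0, 10),
                                 terminal_candidates = c(5, 5),
                                 a1_status = "hypoplastic_or_absent",
                                 acoa_patent = TRUE,
                                 measured_from_contralateral = FALSE)),
    "contralateral carotid angiography")

  contra <- angio_landmarks("c", "right", c(3, 4), c(0, 0), c(0, 10),
                            terminal_candidates = c(5, 5),
                            a1_status = "hypoplastic_or_absent",
                            acoa_patent = TRUE,
                            measured_from_contralateral = TRUE)
  expect_identical(measure_abza(contra)$rule_applied, "contralateral")

  expect_error(angio_landmarks("x", "left", c(3, 4), c(0, 0), c(0, 10),
                               terminal_candidates = c(5, 5),
                               a1_status = "normal",
                               measured_from_contralateral = TRUE),
               "A1 is normal")
  expect_error(angio_landmarks("x", "left", c(3, 4), c(0, 0), c(0, 10),
                               terminal_candidates = NULL,
                               a1_status = "normal"),
               "zero-angle")
})

test_that("measure_abza inverts a constructed phantom and uses the retrograde rule", {
  th <- 57.5 * pi / 180
  lm <- angio_landmarks("p", "left", t_point = c(4, 0),
                        mid_base = c(0, -10), mid_apex = c(0, 10),
                        terminal_candidates = 10 * c(sin(th), cos(th)))
  expect_equal(measure_abza(lm)$abza_deg, 57.5, tolerance = 1e-6)

  two <- angio_landmarks("q", "left", t_point = c(4, 3),
                         mid_base = c(0, -10), mid_apex = c(0, 10),
                         terminal_candidates = rbind(c(2, 6), c(4, 4)),
                         occlusion = "mcao_complete")
  m <- measure_abza(two)
  expect_identical(m$rule_applied, "mcao_retrograde")
  expect_equal(m$terminal_c, c(x = 3, y = 5))
  expect_equal(m$abza_deg,
               angle_from_midline(c(0, 3), c(3, 5), c(0, -10), c(0, 10)))
})

test_that("measurement is invariant to rigid motion, mirroring and scale", {
  set.seed(7)
  thetas <- c(0.1, seq(5, 90, by = 5))
  for (th in thetas) {
    rot <- runif(1, 0, 360); tr <- runif(2, -50, 50)
    plain <- generate_landmarks(phantom_spec(th))
    moved <- generate_landmarks(phantom_spec(th, rotation_deg = rot,
                                             translation = tr))
    expect_lt(abs(measure_abza(plain)$abza_deg - th), 1e-6)
    expect_lt(abs(measure_abza(moved)$abza_deg - th), 1e-6)
    # mirror across the canonical (vertical) midline: negate x
    mir <- plain
    mir$t_point[1] <- -mir$t_point[1]
    mir$terminal_candidates[, 1] <- -mir$terminal_candidates[, 1]
    expect_equal(measure_abza(mir)$abza_deg, measure_abza(plain)$abza_deg,
                 tolerance = 1e-9)
    # uniform scaling about the vertex
    sc <- plain
    sc$terminal_candidates <- sc$terminal_candidates * 3.7
    sc$t_point <- sc$t_point * 3.7
    sc$mid_base <- sc$mid_base * 3.7
    sc$mid_apex <- sc$mid_apex * 3.7
    expect_equal(measure_abza(sc)$abza_deg, measure_abza(plain)$abza_deg,
                 tolerance = 1e-9)
  }
})
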