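test_that("base_from_range back-calculates effective base-case values", {
  # published 75%/125% ranges
  expect_equal(base_from_range(0.0825, 0.1375), 0.11, tolerance = 1e-12)
  expect_equal(base_from_range(0.0344, 0.0573), 0.0459, tolerance = 1e-4 / 0.0459)
  expect_equal(base_from_range(0.75, 1.25), 1.0, tolerance = 1e-12)
  # rounding-aware refinement recovers the value entered in the model
  expect_identical(base_from_range(0.0344, 0.0573, digits = 4), 0.0458)
  expect_identical(base_from_range(0.0825, 0.1375, digits = 4), 0.11)
  expect_identical(base_from_range(0.2678, 0.4464, digits = 4), 0.3571)
  expect_identical(base_from_range(0.3636, 0.6060, digits = 4), 0.4848)
  expect_identical(base_from_range(0.1185, 0.1975, digits = 4), 0.158)
})

test_that("base_from_range round-trips exact 75%/125% ranges", {
  set.seed(11)
  for (x in c(runif(20, 0.001, 0.999), runif(5, 1, 1e5)))
    expect_equal(base_from_range(0.75 * x, 1.25 * x), x, tolerance = 1e-12)
})

test_that("base_from_range flags inconsistent ranges", {
  # absolute (non-multiplicative) band: back-calculations differ by ~2.5%
  expect_warning(v <- base_from_range(0.16, 0.26), "disagree")
  expect_equal(v, (0.16 / 0.75 + 0.26 / 1.25) / 2, tolerance = 1e-12)
  expect_error(base_from_range(0.1, 0.2), "disagree")
  expect_error(base_from_range(0.2, 0.1))
  expect_error(base_from_range(0, 0.1))
})

test_that("beta moment fit reproduces requested moments", {
  expect_equal(unname(beta_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-9)
  sh <- beta_from_moments(0.11, 0.0181)
  expect_equal(unname(sh), c(32.76, 265.06), tolerance = 0.01 / 32)
  # round-trip identity across a grid of feasible (mean, sd)
  for (m in c(0.0458, 0.11, 0.3571, 0.4848, 0.9)) {
    for (s in c(0.3, 0.8) * sqrt(m * (1 - m))) {
      sh <- beta_from_moments(m, s)
      a <- sh[["shape1"]]; b <- sh[["shape2"]]
      expect_equal(a / (a + b), m, tolerance = 1e-12)
      expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), s,
                   tolerance = 1e-9)
    }
  }
  expect_error(beta_from_moments(0.5, 0.6), "overdispersed")
  expect_error(beta_from_moments(1.2, 0.1))
})

test_that("gamma moment fit handles degenerate SD-zero rows", {
  g <- gamma_from_moments(103.69, 0)
  expect_true(g$fixed)
  expect_equal(g$value, 103.69)
  g <- gamma_from_moments(67984, 16996)
  expect_equal(g$shape, 16, tolerance = 1e-9)
  expect_equal(g$scale, 4249, tolerance = 1e-9)
  # round trip shape/scale -> moments -> shape/scale
  for (shape in c(0.5, 4, 16)) for (scale in c(10, 4249)) {
    g <- gamma_from_moments(shape * scale, sqrt(shape) * scale)
    expect_equal(g$shape, shape, tolerance = 1e-9)
    expect_equal(g$scale, scale, tolerance = 1e-9)
  }
  expect_error(gamma_from_moments(-1, 2), "positive")
  expect_error(gamma_from_moments(10, -1))
})

test_that("effective base case substitutes the range-implied probabilities", {
  subs <- substitution_report(eff_cfg)
  expect_setequal(subs$path, c("posaconazole.p_ifi", "sat.p_ifi",
                               "posaconazole.p_death_ifi", "sat.p_death_ifi",
                               "p_death_other"))
  expect_identical(get_param(eff_cfg, "posaconazole.p_ifi"), 0.0458)
  expect_identical(get_param(eff_cfg, "sat.p_ifi"), 0.11)
  expect_identical(get_param(eff_cfg, "posaconazole.p_death_ifi"), 0.3571)
  expect_identical(get_param(eff_cfg, "sat.p_death_ifi"), 0.4848)
  expect_identical(get_param(eff_cfg, "p_death_other"), 0.158)
  # costs untouched
  expect_equal(get_param(eff_cfg, "cost_per_day.posaconazole"), 103.69)
  expect_equal(get_param(eff_cfg, "c_ifi"), 67984)
  # idempotent
  twice <- effective_base_case(eff_cfg)
  expect_identical(get_param(twice, "posaconazole.p_ifi"), 0.0458)
  expect_equal(substitution_report(twice)$effective, subs$effective)
})

test_that("validate_config returns machine-readable violations", {
  expect_identical(nrow(validate_config(base_cfg)), 0L)
  bad <- set_param(base_cfg, "posaconazole.p_ifi", 1.2)
  v <- validate_config(bad)
  # flagged both as an invalid probability and as an infeasible Beta mean
  expect_true(all(v$path == "posaconazole.p_ifi"))
  expect_match(v$rule, "probability", all = FALSE)
  bad <- base_cfg
  bad$strategies$sat$components[[2]]$weight <- 0.20
  v <- validate_config(bad)
  expect_identical(v$path, "sat.components")
  expect_match(v$rule, "sum to 1")
})
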