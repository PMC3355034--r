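test_that("relative survival converts to monthly mortality under constant hazard", {
  expect_identical(monthly_mortality_from_relative_survival(1, 5), 0)
  expect_equal(monthly_mortality_from_relative_survival(0.21, 5),
               1 - exp(log(0.21) / 60), tolerance = 1e-12)
  expect_equal(monthly_mortality_from_relative_survival(0.21, 5), 0.02567,
               tolerance = 1e-4 / 0.0257)
  expect_equal(monthly_mortality_from_relative_survival(0.08, 5), 0.04124,
               tolerance = 1e-4 / 0.0412)
  expect_error(monthly_mortality_from_relative_survival(0, 5), "positive")
  expect_error(monthly_mortality_from_relative_survival(1.2, 5))
})

test_that("discount factor is 1 inside year one, compound beyond", {
  expect_identical(discount_factor(0.5, 0.03), 1)
  expect_equal(discount_factor(2, 0.03), 1.03^-2, tolerance = 1e-12)
  expect_equal(discount_factor(2, 0.03), 0.9426, tolerance = 1e-4)
  expect_identical(discount_factor(c(0, 3, 70), 0), c(1, 1, 1))
})

test_that("Markov engine matches the geometric closed form (constant hazard, no discount)", {
  # oracle: with half-cycle correction, LE in months = (1-q)/q + 1/2
  sh <- eff_cfg$shared
  sh$discount_rate <- 0
  sh$horizon_years <- 200
  sh$rs_mds <- sh$rs_aml       # single hazard so the mixture is degenerate
  q <- monthly_mortality_from_relative_survival(sh$rs_aml, sh$rs_basis_years)
  out <- run_markov(1, sh, acute_life_years = 0)
  expect_equal(out$discounted_le_per_survivor * 12, (1 - q) / q + 0.5,
               tolerance = 1e-6 / 40)
  # and the same identity for the MDS hazard
  sh$rs_aml <- 0.08; sh$rs_mds <- 0.08
  q <- monthly_mortality_from_relative_survival(0.08, sh$rs_basis_years)
  out <- run_markov(1, sh, acute_life_years = 0)
  expect_equal(out$discounted_le_per_survivor * 12, (1 - q) / q + 0.5,
               tolerance = 1e-6 / 24)
})

test_that("discounting shrinks life expectancy within analytic brackets", {
  sh <- eff_cfg$shared
  sh$aml_fraction <- 1          # AML sub-cohort only
  out <- run_markov(1, sh, acute_life_years = 0)
  expect_lt(out$discounted_le_per_survivor, out$undiscounted_le_per_survivor)
  expect_gt(out$discounted_le_per_survivor, 2.0)
  expect_lt(out$undiscounted_le_per_survivor, 3.5)
  expect_lte(out$cycles_run, sh$horizon_years * 12)
})

test_that("no survivors means no lifetime accrual", {
  out <- run_markov(0, eff_cfg$shared, acute_life_years = 0.25)
  expect_identical(out$lys_total, 0.25)
})

test_that("alive fraction is non-increasing and person-time non-negative", {
  out <- run_markov(1, eff_cfg$shared, acute_life_years = 0, trace = TRUE)
  tr <- out$trace
  expect_true(all(diff(tr$alive_aml) <= 0))
  expect_true(all(diff(tr$alive_mds) <= 0))
  expect_true(all(tr$person_years >= 0))
  expect_true(all(tr$discount <= 1 & tr$discount > 0))
  # trace person-years reproduce the mixed discounted LE
  expect_equal(sum(tr$person_years), out$discounted_le_per_survivor,
               tolerance = 1e-9)
})

test_that("LYS is monotone in survival, hazard and discount rate", {
  lys <- function(p_surv, rs_aml = 0.21, rate = 0.03) {
    sh <- eff_cfg$shared
    sh$rs_aml <- rs_aml; sh$discount_rate <- rate
    run_markov(p_surv, sh, acute_life_years = 0.25)$lys_total
  }
  expect_true(all(diff(vapply(seq(0, 1, 0.2), lys, numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.1, 0.21, 0.4), function(r)
    lys(0.8, rs_aml = r), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0, 0.03, 0.05), function(r)
    lys(0.8, rate = r), numeric(1))) < 0))
  expect_error(run_markov(0.8, modifyList(eff_cfg$shared,
                                          list(horizon_years = 0)), 0.25))
})

test_that("higher 100-day survival always yields higher LYS (same lifetime params)", {
  for (af in c(0, 0.5, 1)) {
    sh <- eff_cfg$shared
    sh$aml_fraction <- af
    posa <- run_decision_tree(eff_cfg$strategies$posaconazole, sh)
    sat <- run_decision_tree(eff_cfg$strategies$sat, sh)
    lp <- run_markov(posa$p_survive_100d, sh, posa$acute_life_years)$lys_total
    ls <- run_markov(sat$p_survive_100d, sh, sat$acute_life_years)$lys_total
    expect_gt(lp, ls)
  }
})
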