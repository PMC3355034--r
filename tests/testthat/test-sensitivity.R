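test_that("one-way DSA runs the default grid and reproduces dominance", {
  dsa <- run_dsa(base_cfg)
  expect_identical(nrow(dsa), 24L)
  expect_identical(length(unique(dsa$parameter)), 12L)
  # dominance everywhere except where the arms' IFI-probability gap shrinks
  # below the prophylaxis cost difference (2,557.50 / 67,984 = 0.0376)
  flagged <- dsa[!dsa$dominant, ]
  expect_setequal(paste(flagged$parameter, flagged$value),
                  c("posaconazole.p_ifi 0.075", "sat.p_ifi 0.075"))
  expect_true(all(flagged$delta_cost > 0))
  expect_true(all(flagged$delta_ifis_avoided > 0))
  expect_true(all(flagged$classification_lys == "tradeoff_icer"))
  # discount-rate scenarios in particular stay dominant
  expect_true(all(dsa$dominant[dsa$parameter == "discount_rate"]))
  expect_error(run_dsa(base_cfg, scenarios = list(bogus = c(1, 2))),
               "unknown parameter")
})

test_that("PSA with all SDs forced to zero collapses to the base case", {
  cfg <- eff_cfg
  for (p in names(cfg$psa)) cfg$psa[[p]] <- list(family = "fixed", sd = 0)
  psa <- run_psa(cfg, n_draws = 50, seed = 1)
  bc <- run_base_case(eff_cfg)
  expect_equal(unique(psa$draws$delta_cost), bc$comparison$delta_cost,
               tolerance = 1e-12)
  expect_identical(psa$p_cost_saving, 1)
})

test_that("PSA is bit-reproducible under a fixed seed", {
  a <- run_psa(base_cfg, n_draws = 500, seed = 99)
  b <- run_psa(base_cfg, n_draws = 500, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$p_cost_saving, b$p_cost_saving)
})

test_that("sampled parameter means match their specs", {
  n <- 50000
  psa <- run_psa(base_cfg, n_draws = n, seed = 5)
  checks <- list(c("posaconazole.p_ifi", 0.0458, 0.0120),
                 c("sat.p_ifi", 0.11, 0.0181),
                 c("sat.p_death_ifi", 0.4848, 0.0857),
                 c("p_death_other", 0.158, 0.0148),
                 c("c_ifi", 67984, 0.25 * 67984))
  for (ck in checks) {
    x <- psa$draws[[ck[1]]]
    m <- as.numeric(ck[2]); s <- as.numeric(ck[3])
    expect_equal(mean(x), m, tolerance = 3 * s / sqrt(n) / m)
  }
})

test_that("fixed-cost PSA matches the closed-form normal approximation", {
  # with c_ifi fixed, posaconazole is cheaper iff pS - pP > 2557.50/67984;
  # a normal approximation of the Beta difference gives the oracle
  psa <- run_psa(base_cfg, n_draws = 40000, seed = 21, fix = "c_ifi")
  dproph <- 29 * 103.69 - (0.81 * 24 * 16.93 + 0.19 * 29 * 21.85)
  oracle <- pnorm((0.0642 - dproph / 67984) / sqrt(0.0120^2 + 0.0181^2))
  expect_equal(psa$p_cost_saving, oracle, tolerance = 0.02 / oracle)
})

test_that("Monte Carlo error halves when draws quadruple", {
  se_of <- function(n, reps = 12) {
    ps <- vapply(seq_len(reps), function(i)
      run_psa(eff_cfg, n_draws = n, seed = 1000 + i)$p_cost_saving, numeric(1))
    stats::sd(ps)
  }
  # SE ~ 1/sqrt(n): quadrupling n should halve it (generous band)
  expect_equal(se_of(4000) / se_of(1000), 0.5, tolerance = 0.6)
})

test_that("CEAC starts at p(cost-saving) and rises towards one", {
  psa <- run_psa(base_cfg, n_draws = 5000, seed = 3)
  grid <- seq(0, 60000, by = 5000)
  cc <- ceac(psa, grid)
  expect_identical(cc$probability[1], psa$p_cost_saving)
  expect_equal(cc$probability[cc$threshold == 30000], psa$p_below_threshold)
  if (all(psa$draws$delta_lys > 0))
    expect_true(all(diff(cc$probability) >= 0))
  big <- ceac(psa, c(0, 1e9))$probability[2]
  expect_equal(big, mean(psa$draws$delta_lys > 0 |
                           (psa$draws$delta_lys == 0 & psa$draws$delta_cost < 0)))
  # acceptability at the Spanish threshold exceeds the cost-saving probability
  expect_gt(psa$p_below_threshold, psa$p_cost_saving)
})

test_that("crossover analysis reproduces the threshold findings", {
  co <- crossover_benefit(base_cfg)
  expect_identical(co$status, "crossover")
  # identical IFI probabilities: SAT dominant (posaconazole dominated)
  row0 <- co$table[co$table$dp == 0, ]
  expect_identical(row0$classification, "dominated")
  expect_gt(row0$delta_cost, 0)
  # at a 2% absolute risk reduction the ICER exceeds the threshold
  row2 <- co$table[co$table$dp == 0.02, ]
  expect_identical(row2$classification, "tradeoff_icer")
  expect_false(row2$cost_effective)
  expect_gt(as.numeric(row2$icer_per_lys), 30000)
  # at the base-case 6% reduction posaconazole is dominant
  row6 <- co$table[co$table$dp == 0.06, ]
  expect_identical(row6$classification, "dominant")
  # the crossover sits between the two
  expect_gt(co$dp_star, 0.02)
  expect_lt(co$dp_star, co$dp_base)
})
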