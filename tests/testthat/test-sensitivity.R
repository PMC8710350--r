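# One-way DSA, PSA draws, and acceptability curves.

psa_toy <- function() {
  p <- toy_params(p_rec = c(rep(0.04, 24), rep(0, 36)), p_crc = 0.06,
                  q_annual = 0, tunnel_depth = 4,
                  disability_weights = list(disease_free = 0, recurrence = 0.3,
                                            hepatectomy = 0,
                                            hepatectomy_months = 0),
                  discount = 0.05)
  p$recurrence_prob$CAPOX_3MO[] <- 0
  p$psa <- list(cv = 0.2, components = list(hazard = 0, weights = 0,
                                            costs = 0, trae = 0,
                                            crc_death = 0.2))
  p
}

test_that("degenerate ranges produce zero swing; endpoints match re-runs", {
  params <- psa_toy()
  params$costs$adjuvant$CAPOX_3MO["drug"] <- 150
  strategies <- toy_strategies()
  wtp <- 50  # below the treatment ICER at both endpoints, so the
             # comparator stays optimal and the tornado outcome is defined

  r0 <- dsa_range("costs.adjuvant.CAPOX_3MO.drug", 150, 150)
  out <- one_way_dsa(list(r0), params, strategies, wtp)
  expect_equal(out$swing, 0)
  expect_equal(out$icer_low, out$icer_base)
  expect_false(out$optimal_changed)

  r1 <- dsa_range("costs.adjuvant.CAPOX_3MO.drug", 50, 400)
  out <- one_way_dsa(list(r1), params, strategies, wtp)
  # independent recomputation of each endpoint through the full analysis
  for (v in c(50, 400)) {
    p2 <- param_set(params, "costs.adjuvant.CAPOX_3MO.drug", v)
    res <- run_cea(p2, strategies, wtp)
    front <- res[res$dominance == "on_frontier", ]
    front <- front[order(front$dalys_averted), ]
    opt <- select_optimal(res, wtp)
    i <- match(opt, front$strategy)
    expected <- if (i == nrow(front)) NA_real_ else front$icer[i + 1]
    got <- if (v == 50) out$icer_low else out$icer_high
    expect_equal(got, expected)
  }
  expect_gt(out$swing, 0)
})

test_that("raising a cost parameter strictly increases lifetime cost", {
  params <- psa_toy()
  strat <- toy_strategies()$CAPOX_3MO
  tr <- run_cohort(strat, params)
  base_cost <- accrue_costs(tr, strat, params)
  p2 <- param_set(params, "costs.adjuvant.CAPOX_3MO.drug", 500)
  expect_gt(accrue_costs(tr, strat, p2), base_cost)
})

test_that("DSA rejects out-of-bound parameter values", {
  params <- psa_toy()
  expect_error(
    one_way_dsa(list(dsa_range("disability_weights.recurrence", 0.2, 1.5)),
                params, toy_strategies(), 2000),
    "\\[0,1\\]")
  expect_error(dsa_range("x", 2, 1), "low > high")
})

test_that("the WTP and hazard-factor special paths work", {
  params <- psa_toy()
  params$costs$adjuvant$CAPOX_3MO["drug"] <- 150
  mod <- colcea:::apply_dsa_value(params, 2000, "wtp", 9999)
  expect_equal(mod$wtp, 9999)
  mod <- colcea:::apply_dsa_value(params, 2000,
                                  "recurrence_hazard_factor.NO_CHEMO", 1.2)
  p0 <- params$recurrence_prob$NO_CHEMO
  expect_equal(mod$params$recurrence_prob$NO_CHEMO, 1 - (1 - p0)^1.2)
})

test_that("parameter draws are reproducible and collapse when degenerate", {
  params <- psa_toy()
  d0 <- draw_parameter_set(params, cv = 0, components = NULL)
  expect_identical(d0, params)

  set.seed(5)
  d1 <- draw_parameter_set(params)
  set.seed(5)
  d2 <- draw_parameter_set(params)
  expect_identical(d1, d2)
  validate_parameters(d1)
  # only the post-recurrence mortality block varies in this toy PSA spec
  expect_identical(d1$costs, params$costs)
  expect_identical(d1$recurrence_prob, params$recurrence_prob)
  expect_false(identical(d1$crc_death_prob, params$crc_death_prob))
})

test_that("beta and gamma draws match their configured moments", {
  set.seed(31)
  m <- 0.3; cv <- 0.2
  x <- colcea:::beta_draw(10000, m, cv)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - m), 3 * stats::sd(x) / sqrt(10000))
  expect_equal(stats::sd(x) / mean(x), cv, tolerance = 0.05)
  y <- colcea:::gamma_draw(10000, 250, cv)
  expect_true(all(y > 0))
  expect_lt(abs(mean(y) - 250), 3 * stats::sd(y) / sqrt(10000))
})

test_that("drawn parameter sets always satisfy the validation suite", {
  params <- default_params()
  set.seed(77)
  for (i in 1:50) expect_silent(validate_parameters(draw_parameter_set(params)))
})

test_that("PSA handles single-strategy and degenerate cases", {
  params <- psa_toy()
  one <- run_psa(params, default_strategies("NO_CHEMO"), n = 5, seed = 3,
                 wtp = 2000)
  expect_equal(unname(one$probability_optimal["NO_CHEMO"]), 1)

  params$psa$components$crc_death <- 0
  det <- run_psa(params, toy_strategies(), n = 10, seed = 3, wtp = 2000,
                 cv = 0)
  base <- run_cea(params, toy_strategies(), 2000)
  expect_equal(unname(det$probability_optimal[attr(base, "optimal")]), 1)
  expect_equal(unname(det$cost[1, ]), base$cost, tolerance = 1e-12)
})

test_that("PSA is bit-identical across runs with the same seed", {
  params <- psa_toy()
  a <- run_psa(params, toy_strategies(), n = 40, seed = 11, wtp = 2000)
  b <- run_psa(params, toy_strategies(), n = 40, seed = 11, wtp = 2000)
  expect_identical(a$cost, b$cost)
  expect_identical(a$probability_optimal, b$probability_optimal)
  c2 <- run_psa(params, toy_strategies(), n = 40, seed = 12, wtp = 2000)
  expect_false(identical(a$effect, c2$effect))
})

test_that("CEAC normalizes, matches the PSA summary, and concentrates", {
  params <- psa_toy()
  params$costs$adjuvant$CAPOX_3MO["drug"] <- 150
  psa <- run_psa(params, toy_strategies(), n = 100, seed = 21, wtp = 2000)
  grid <- c(500, 2000, 8000)
  cc <- ceac(psa, grid)
  sums <- as.numeric(tapply(cc$probability, cc$wtp, sum))
  expect_equal(sums, rep(1, length(grid)), tolerance = 1e-9)
  # a one-point grid reproduces run_psa's own summary
  cc1 <- ceac(psa, 2000)
  expect_equal(cc1$probability[match(names(psa$probability_optimal), cc1$strategy)],
               unname(psa$probability_optimal), tolerance = 1e-12)
  # WTP -> infinity concentrates on the per-iteration max-effect strategy
  cc_inf <- ceac(psa, 1e12)
  eff_win <- colnames(psa$effect)[max.col(psa$effect, ties.method = "first")]
  expect_equal(cc_inf$probability[cc_inf$strategy == "CAPOX_3MO"],
               mean(eff_win == "CAPOX_3MO"))
})
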