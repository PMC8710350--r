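# Discounting, currency, cost and DALY accrual, frontier/ICER/NMB.

test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(12, 0.05), 1 / 1.05, tolerance = 1e-9)
  expect_equal(discount_factor(24, 0.05), 1 / 1.05^2, tolerance = 1e-9)
  expect_equal(discount_factor(6, 0), 1)
  expect_error(discount_factor(-1), ">= 0")
  # discounting identity: discounted <= undiscounted, equality iff rate 0
  x <- runif(50)
  expect_lte(sum(x * discount_factor(1:50, 0.05)), sum(x))
  expect_equal(sum(x * discount_factor(1:50, 0)), sum(x))
})

test_that("currency conversion uses the fixed PPP factor", {
  expect_equal(zar_to_intl(6.86), 1)
  expect_equal(zar_to_intl(0), 0)
  expect_equal(zar_to_intl(686), 100)
  expect_equal(intl_to_zar(zar_to_intl(123.45)), 123.45, tolerance = 1e-12)
  expect_error(zar_to_intl(-1), ">= 0")
})

test_that("indirect visit costs cover transport and wages for two people", {
  ind <- list(transport_round_trip = 6.03, hourly_wage = 2.52,
              hours_per_visit = 8, persons = 2)
  expect_equal(colcea:::indirect_cost_per_visit(ind), (6.03 + 8 * 2.52) * 2)
  expect_equal(colcea:::indirect_cost_per_visit(ind), 52.38)
})

test_that("cost accrual matches a hand-computed toy integral", {
  # flat surveillance cost c per disease-free month, no deaths until the
  # terminal forcing, no discounting: cost = c * trapezoidal person-months
  cc <- 37.5
  params <- toy_params(p_rec = 0, p_crc = 0, q_annual = 0)
  params$costs$surveillance_monthly <- cc
  strat <- toy_strategies()$NO_CHEMO
  tr <- run_cohort(strat, params)
  expect_equal(accrue_costs(tr, strat, params), cc * (60 - 0.5))

  # NO_CHEMO with all costs zero -> 0
  params$costs$surveillance_monthly <- 0
  expect_equal(accrue_costs(tr, strat, params), 0)
})

test_that("adjuvant, indirect and metastatic components accrue as specified", {
  params <- toy_params(p_rec = 0, p_crc = 0, q_annual = 0)
  strat <- toy_strategies()$CAPOX_3MO
  # adjuvant component: 3 months of (drug 100) while everyone is disease-free
  params$costs$adjuvant$CAPOX_3MO["drug"] <- 100
  tr <- run_cohort(strat, params)
  expect_equal(accrue_costs(tr, strat, params), 100 * 3, tolerance = 1e-9)

  # indirect: 4 visits over a 3-month course at 52.38 per visit
  params$costs$adjuvant$CAPOX_3MO["drug"] <- 0
  params$costs$indirect <- list(transport_round_trip = 6.03, hourly_wage = 2.52,
                                hours_per_visit = 8, persons = 2)
  expect_equal(accrue_costs(tr, strat, params), 4 * 52.38, tolerance = 1e-9)

  # metastatic line costs: everyone recurs in month 1 (EARLY), line 1 only
  params2 <- toy_params(p_rec = c(1, rep(0, 59)), p_crc = 0, q_annual = 0,
                        tunnel_depth = 20)
  params2$costs$metastatic$line1_monthly <- 10
  tr2 <- run_cohort(toy_strategies()$CAPOX_3MO, params2)
  # entire cohort spends months 2..60 in recurrence; line 1 covers tunnel
  # months 0..5, entered at cycles 1..6, with half-cycle edges
  w <- half_cycle_weights(tr2)
  expect_equal(accrue_costs(tr2, toy_strategies()$CAPOX_3MO, params2),
               10 * (0.5 + 5 + 0.5), tolerance = 1e-9)
})

test_that("hepatectomy applies its one-time cost to one ninth of entries", {
  params <- toy_params(p_rec = c(1, rep(0, 59)), p_crc = 0, q_annual = 0)
  params$costs$hepatectomy <- 900
  strat <- toy_strategies()$CAPOX_3MO
  tr <- run_cohort(strat, params)
  expect_equal(accrue_costs(tr, strat, params), 900 / 9, tolerance = 1e-9)
})

test_that("DALY accrual matches hand arithmetic", {
  # all weights zero, no CRC deaths -> 0 DALYs
  params <- toy_params(p_rec = 0, p_crc = 0, q_annual = 0)
  strat <- toy_strategies()$NO_CHEMO
  tr <- run_cohort(strat, params)
  expect_equal(compute_dalys(tr, params$disability_weights, strat, params), 0)

  # weight-1 year: entire cohort in DeathCRC for 12 undiscounted months
  # accrues exactly 1 DALY of years of life lost
  params2 <- toy_params(start_age = 84, tunnel_depth = 2,
                        p_rec = c(1, rep(0, 11)), p_crc = 1, q_annual = 0)
  strat2 <- toy_strategies()$CAPOX_3MO
  tr2 <- run_cohort(strat2, params2)
  # recurrence at cycle 1, CRC death at cycle 2, in DeathCRC cycles 2..12
  yll_months <- sum(half_cycle_weights(tr2)[, "DeathCRC"])
  expect_equal(compute_dalys(tr2, params2$disability_weights, strat2, params2),
               yll_months / 12)
  expect_equal(yll_months, 10.5)

  # recurrence weight 0.2 for 24 undiscounted person-months -> 0.4 DALYs
  params3 <- toy_params(start_age = 82, tunnel_depth = 40,
                        p_rec = c(1, rep(0, 35)), p_crc = 0, q_annual = 0,
                        disability_weights = list(disease_free = 0,
                                                  recurrence = 0.2,
                                                  hepatectomy = 0,
                                                  hepatectomy_months = 0))
  tr3 <- run_cohort(strat2, params3)
  w_rec <- half_cycle_weights(tr3)
  rec_cols <- grep("^Rec_", colnames(tr3$occupancy))
  # entered at cycle 1, alive until the terminal forcing at month 36:
  # 0.5 + 34 + 0.5 = 35 undiscounted person-months at weight 0.2
  expect_equal(sum(w_rec[, rec_cols]), 35)
  part <- compute_dalys(tr3, params3$disability_weights, strat2, params3)
  expect_equal(part, 0.2 * 35 / 12, tolerance = 1e-12)
})

test_that("dalys averted is the comparator difference", {
  expect_equal(dalys_averted(10, 10), 0)
  expect_equal(dalys_averted(4.0, 9.74), 5.74)
  expect_equal(dalys_averted(4 + 1.3, 9.74 + 1.3), 5.74, tolerance = 1e-12)
})

test_that("net monetary benefit is the exact formula", {
  expect_equal(nmb(13006.56, 0, 0), 0)
  expect_equal(nmb(10, 2, 5), 15)
  set.seed(7)
  for (i in 1:50) {
    w <- runif(1, 0, 5e4); e <- runif(1, -2, 8); cst <- runif(1, 0, 3e4)
    expect_identical(nmb(w, e, cst), w * e - cst)
  }
})

test_that("two-point frontier yields the pairwise ICER", {
  res <- frontier_and_icers(data.frame(strategy = c("A", "B"),
                                       cost = c(0, 10), effect = c(0, 1)))
  expect_equal(res$dominance, c("on_frontier", "on_frontier"))
  expect_equal(res$icer, c(NA, 10))
})

test_that("published base-case pairs reproduce the reported dominance", {
  res <- frontier_and_icers(data.frame(
    strategy = c("NO_CHEMO", "CAPOX_3MO", "FOLFOX_6MO"),
    cost = c(9959.24, 5381.17, 22747.82),
    effect = c(0, 5.74, 5.91)))
  expect_equal(res$dominance[res$strategy == "NO_CHEMO"], "strongly_dominated")
  expect_equal(res$dominance[res$strategy == "CAPOX_3MO"], "on_frontier")
  expect_equal(res$dominance[res$strategy == "FOLFOX_6MO"], "on_frontier")
  icer_f6 <- res$icer[res$strategy == "FOLFOX_6MO"]
  expect_equal(icer_f6, (22747.82 - 5381.17) / (5.91 - 5.74), tolerance = 1e-9)
  expect_gt(icer_f6, 13006.56)
  expect_equal(select_optimal(res, 13006.56), "CAPOX_3MO")
})

test_that("frontier equals the brute-force oracle on random instances", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    d <- data.frame(strategy = paste0("S", 1:n),
                    cost = runif(n, 0, 100), effect = runif(n, 0, 10))
    res <- frontier_and_icers(d)
    expect_equal(res$dominance == "on_frontier", oracle_frontier(d$cost, d$effect),
                 info = paste("instance", i))
    front <- res[res$dominance == "on_frontier", ]
    front <- front[order(front$effect), ]
    if (nrow(front) >= 3) {
      ic <- front$icer[-1]
      expect_true(all(diff(ic) > 0), info = paste("icer monotone", i))
    }
  }
})

test_that("NMB argmax equals the frontier-ICER selection rule", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    d <- data.frame(strategy = paste0("S", 1:n),
                    cost = runif(n, 0, 100), effect = runif(n, 0, 10))
    w <- runif(1, 0.1, 50)
    opt <- select_optimal(d, w)
    res <- frontier_and_icers(d)
    front <- res[res$dominance == "on_frontier", ]
    front <- front[order(front$effect), ]
    ic <- c(-Inf, front$icer[-1])
    rule <- front$strategy[max(which(ic <= w))]
    expect_identical(opt, rule, info = paste("instance", i))
  }
})

test_that("frontier input validation and tie handling", {
  expect_error(frontier_and_icers(data.frame(strategy = c("A", "A"),
                                             cost = 1:2, effect = 1:2)),
               "duplicate")
  expect_error(frontier_and_icers(data.frame(strategy = "A", cost = 1,
                                             effect = 1)),
               "at least two")
  res <- frontier_and_icers(data.frame(strategy = c("A", "B", "C"),
                                       cost = c(5, 5, 9), effect = c(1, 1, 2)))
  expect_true(all(res$equivalent[res$strategy %in% c("A", "B")]))
  expect_equal(res$dominance, rep("on_frontier", 3))
})

test_that("DALYs stay within the discounted-horizon bound", {
  params <- default_params()
  horizon_years <- sum(discount_factor(1:300 - 0.5, params$discount_rate_annual)) / 12
  for (s in c("NO_CHEMO", "CAPOX_3MO")) {
    st <- default_strategies()[[s]]
    tr <- run_cohort(st, params)
    d <- compute_dalys(tr, params$disability_weights, st, params)
    expect_gte(d, 0)
    expect_lte(d, horizon_years)
  }
})
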