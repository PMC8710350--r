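# Shared fixtures: small hand-checkable parameter sets and independent
# oracles. Everything is generated in code; no stored data.

# default synthetic parameter set, built once per test run
default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_parameter_set(synthetic_scenario())
    cache
  }
})

zero_trae_tab <- function() {
  data.frame(event = c("neutropenia", "diarrhea", "nausea_vomiting",
                       "peripheral_neuropathy", "hand_foot_syndrome", "fatigue"),
             probability = 0, cost = 0, weight = 0, duration_months = 0)
}

# Minimal parameter set with hand-set probabilities and (by default) zero
# costs/weights. start_age 80 gives a 60-month horizon, keeping toy models
# cheap. Flat recurrence/CRC-death probabilities; flat life table until the
# forced 1.0 at 85.
toy_params <- function(start_age = 80,
                       tunnel_depth = 4,
                       p_rec = 0.02,
                       p_crc = 0.04,
                       q_annual = 0,
                       cure_month = NULL,
                       strategies = c("NO_CHEMO", "CAPOX_3MO"),
                       disability_weights = list(disease_free = 0, recurrence = 0,
                                                 hepatectomy = 0,
                                                 hepatectomy_months = 0),
                       costs = NULL,
                       trae = NULL,
                       discount = 0,
                       wtp = 13006.56) {
  horizon <- 12L * (85L - start_age)
  if (is.null(cure_month)) cure_month <- horizon
  rec <- lapply(stats::setNames(strategies, strategies), function(s) {
    p <- if (s == "NO_CHEMO" && length(strategies) > 1 && length(p_rec) == 1)
      rep(p_rec, horizon) else rep(p_rec, length.out = horizon)
    if (cure_month < horizon) p[(cure_month + 1):horizon] <- 0
    p
  })
  cd <- matrix(p_crc, nrow = 3, ncol = tunnel_depth,
               dimnames = list(c("EARLY", "MID", "LATE"), NULL))
  lt <- data.frame(age = start_age:85,
                   annual_probability = c(rep(q_annual, 85 - start_age), 1))
  if (is.null(costs)) {
    costs <- list(
      adjuvant = lapply(stats::setNames(strategies, strategies),
                        function(s) c(drug = 0, personnel = 0, administration = 0,
                                      antiemetics = 0, bloodwork = 0)),
      surveillance_monthly = 0, surveillance_visits_per_month = 0,
      metastatic = list(line1_monthly = 0, line2_monthly = 0, bsc_monthly = 0,
                        visits_per_month = 0),
      hepatectomy = 0,
      indirect = list(transport_round_trip = 0, hourly_wage = 0,
                      hours_per_visit = 0, persons = 0)
    )
  }
  if (is.null(trae)) {
    trae <- list(
      adjuvant = lapply(stats::setNames(strategies, strategies),
                        function(s) zero_trae_tab()),
      metastatic = list(line1 = zero_trae_tab(), line2 = zero_trae_tab())
    )
  }
  cea_parameters(
    start_age = start_age, horizon_months = horizon, cure_month = cure_month,
    discount_rate_annual = discount, tunnel_depth = tunnel_depth,
    recurrence_prob = rec, crc_death_prob = cd, background_mortality = lt,
    disability_weights = disability_weights, costs = costs, trae = trae,
    wtp = wtp
  )
}

toy_strategies <- function(names = c("NO_CHEMO", "CAPOX_3MO")) {
  default_strategies(names)
}

# annual probability whose monthly equivalent is exactly p_month
annual_from_monthly <- function(p_month) 1 - (1 - p_month)^12

# Independent frontier oracle: textbook pairwise/segment dominance check.
# A point is off the frontier if another point weakly dominates it
# (strictly better in one dimension), or if the segment between two other
# points achieves its effect at strictly lower cost.
oracle_frontier <- function(cost, eff) {
  n <- length(cost)
  on <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && cost[j] <= cost[i] && eff[j] >= eff[i] &&
          (cost[j] < cost[i] || eff[j] > eff[i])) {
        on[i] <- FALSE
      }
    }
    if (!on[i]) next
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        if (eff[j] <= eff[i] && eff[i] <= eff[k] && eff[k] > eff[j]) {
          lam <- (eff[i] - eff[j]) / (eff[k] - eff[j])
          c_interp <- cost[j] + lam * (cost[k] - cost[j])
          if (c_interp < cost[i] - 1e-12) on[i] <- FALSE
        }
      }
    }
  }
  on
}
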