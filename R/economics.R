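# Economics: discounting, currency conversion, societal cost and DALY
# accrual over a cohort trace, and the comparative analysis (efficiency
# frontier, ICERs, net monetary benefit).

ZAR_PER_INTL <- 6.86  # 2020 purchasing-power-parity factor, ZAR per I$

#' Discount factor for a model month
#'
#' `(1 + rate)^(-month/12)`, applied identically to costs and health
#' outcomes. Accrual routines evaluate it at mid-cycle (month `m - 0.5` for
#' model month `m`), consistent with half-cycle-corrected occupancy.
#'
#' @param month Months since model start (>= 0; may be fractional).
#' @param annual_rate Annual discount rate (default 0.05).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(month, annual_rate = 0.05) {
  if (any(month < 0)) stop("month must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-month / 12)
}

#' Convert South African rand to international dollars
#'
#' Fixed 2020 purchasing-power-parity conversion: ZAR 6.86 = I$1.
#'
#' @param amount Amount in ZAR (>= 0).
#' @return Amount in I$.
#' @export
zar_to_intl <- function(amount) {
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  amount / ZAR_PER_INTL
}

#' @rdname zar_to_intl
#' @export
intl_to_zar <- function(amount) {
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  amount * ZAR_PER_INTL
}

# Indirect (societal) cost of one clinic visit: round-trip transport plus a
# day of lost wages, for the patient and caregiver(s).
indirect_cost_per_visit <- function(indirect) {
  (indirect$transport_round_trip +
     indirect$hours_per_visit * indirect$hourly_wage) * indirect$persons
}

# Expected one-off TRAE cost (sum of probability x unit cost) and expected
# disability-weight-months over a treatment course.
trae_expected <- function(tab) {
  list(cost = sum(tab$probability * tab$cost),
       weight_months = sum(tab$probability * tab$weight * tab$duration_months))
}

# Monthly cost rate for the disease-free state (length-horizon vector) and
# for each recurrence tunnel month (length-depth vector).
state_cost_rates <- function(strategy, params, schedule) {
  H <- params$horizon_months
  depth <- params$tunnel_depth
  ind_visit <- indirect_cost_per_visit(schedule$indirect)
  dur <- strategy$adjuvant_duration_months

  adj <- schedule$adjuvant[[strategy$name]]
  if (is.null(adj))
    stop("cost schedule has no adjuvant entry for ", strategy$name, call. = FALSE)

  c_df <- rep(schedule$surveillance_monthly +
                schedule$surveillance_visits_per_month * ind_visit, H)
  if (dur > 0) {
    tr <- trae_expected(params$trae$adjuvant[[strategy$name]])
    c_df[seq_len(dur)] <- sum(adj) + tr$cost / dur +
      (strategy$n_treatment_visits / dur) * ind_visit
  }

  met <- schedule$metastatic
  for (nm in c("line1_monthly", "line2_monthly", "bsc_monthly"))
    if (is.null(met[[nm]]))
      stop("cost schedule missing metastatic$", nm, call. = FALSE)
  visits_pm <- met$visits_per_month %||% 1
  L1 <- params$line1_months
  L2 <- params$line2_months
  tr1 <- trae_expected(params$trae$metastatic$line1)
  tr2 <- trae_expected(params$trae$metastatic$line2)
  k <- seq_len(depth) - 1L
  c_rec <- ifelse(k < L1,
                  met$line1_monthly + tr1$cost / L1 + visits_pm * ind_visit,
                  ifelse(k < L1 + L2,
                         met$line2_monthly + tr2$cost / L2 + visits_pm * ind_visit,
                         met$bsc_monthly))
  list(df = c_df, rec = c_rec)
}

#' Lifetime discounted societal cost of a strategy
#'
#' Sums discounted, half-cycle-corrected monthly costs over the trace:
#' adjuvant regimen costs (drug, personnel, administration, antiemetics,
#' bloodwork), expected adjuvant TRAE costs spread over the course, and
#' per-visit indirect costs (transport plus lost wages for patient and
#' caregiver) during treatment months; surveillance plus indirect visit
#' costs during disease-free follow-up; metastatic line costs (two lines
#' then best supportive care) with expected metastatic TRAE costs in
#' recurrence; and the one-time hepatectomy cost applied to the
#' liver-only-resectable fraction of new recurrence entries.
#'
#' @param trace A `cohort_trace`.
#' @param strategy The matching `cea_strategy`.
#' @param params A `cea_parameters` object.
#' @param schedule Cost schedule (default `params$costs`).
#' @return Lifetime cost in discounted I$.
#' @export
accrue_costs <- function(trace, strategy, params, schedule = params$costs) {
  stopifnot(identical(trace$strategy, strategy$name))
  H <- trace$horizon
  space <- trace$space
  w <- half_cycle_weights(trace)
  disc <- discount_factor(seq_len(H) - 0.5, params$discount_rate_annual)
  rates <- state_cost_rates(strategy, params, schedule)

  cost_df <- sum(disc * w[, space$idx_df] * rates$df)
  # cost rates are stratum-independent: pool tunnel weights across strata
  w_rec <- w[, as.vector(space$idx_rec[1, ]), drop = FALSE] +
    w[, as.vector(space$idx_rec[2, ]), drop = FALSE] +
    w[, as.vector(space$idx_rec[3, ]), drop = FALSE]
  cost_rec <- sum(disc * (w_rec %*% rates$rec))

  hep_frac <- params$liver_only_fraction * params$hepatectomy_fraction_of_liver_only
  flux0 <- rowSums(trace$entry_flux[2:(H + 1L), space$idx_rec[, 1L], drop = FALSE])
  cost_hep <- sum(disc * flux0) * hep_frac * schedule$hepatectomy

  cost_df + cost_rec + cost_hep
}

#' Discounted disability-adjusted life-years of a strategy
#'
#' `DALY = YLD + YLL`, computed without age-weighting on the scale where a
#' disability weight of 0 is full health and 1 equals death from colon
#' cancer. YLD accrues half-cycle-corrected, discounted person-time in the
#' alive states at their weights: the disease-free weight plus transient
#' expected TRAE disability spread over adjuvant treatment months, and the
#' recurrence weight plus metastatic TRAE disability during treatment
#' lines, plus the one-time hepatectomy disability applied to the resected
#' fraction of recurrence entries. YLL accrues person-time in the
#' colon-cancer death state at weight 1 from death until the horizon (age
#' 85); deaths from other causes accrue nothing.
#'
#' @param trace A `cohort_trace`.
#' @param weights Disability-weight list (default
#'   `params$disability_weights`).
#' @param strategy The matching `cea_strategy`.
#' @param params A `cea_parameters` object.
#' @return Discounted DALYs.
#' @export
compute_dalys <- function(trace, weights = params$disability_weights, strategy,
                          params) {
  stopifnot(identical(trace$strategy, strategy$name))
  for (nm in c("disease_free", "recurrence", "hepatectomy")) {
    if (weights[[nm]] < 0 || weights[[nm]] > 1)
      stop("disability weight '", nm, "' outside [0,1]", call. = FALSE)
  }
  H <- trace$horizon
  space <- trace$space
  depth <- space$tunnel_depth
  w <- half_cycle_weights(trace)
  disc <- discount_factor(seq_len(H) - 0.5, params$discount_rate_annual)
  dur <- strategy$adjuvant_duration_months

  w_df_state <- rep(weights$disease_free, H)
  if (dur > 0) {
    tr <- trae_expected(params$trae$adjuvant[[strategy$name]])
    w_df_state[seq_len(dur)] <- w_df_state[seq_len(dur)] + tr$weight_months / dur
  }

  L1 <- params$line1_months
  L2 <- params$line2_months
  tr1 <- trae_expected(params$trae$metastatic$line1)
  tr2 <- trae_expected(params$trae$metastatic$line2)
  k <- seq_len(depth) - 1L
  w_rec_state <- weights$recurrence +
    ifelse(k < L1, tr1$weight_months / L1,
           ifelse(k < L1 + L2, tr2$weight_months / L2, 0))
  w_rec_state <- pmin(1, w_rec_state)

  w_rec <- w[, as.vector(space$idx_rec[1, ]), drop = FALSE] +
    w[, as.vector(space$idx_rec[2, ]), drop = FALSE] +
    w[, as.vector(space$idx_rec[3, ]), drop = FALSE]

  yld <- sum(disc * (w[, space$idx_df] * w_df_state + w_rec %*% w_rec_state)) / 12
  yll <- sum(disc * w[, space$idx_death_crc]) / 12

  hep_frac <- params$liver_only_fraction * params$hepatectomy_fraction_of_liver_only
  flux0 <- rowSums(trace$entry_flux[2:(H + 1L), space$idx_rec[, 1L], drop = FALSE])
  yld_hep <- sum(disc * flux0) * hep_frac *
    weights$hepatectomy * weights$hepatectomy_months / 12

  yld + yll + yld_hep
}

#' DALYs averted relative to the comparator
#'
#' @param strategy_dalys DALYs of the strategy.
#' @param comparator_dalys DALYs of the comparator (no adjuvant
#'   chemotherapy), computed under the identical parameter set.
#' @return `comparator_dalys - strategy_dalys` (positive = health gained).
#' @export
dalys_averted <- function(strategy_dalys, comparator_dalys) {
  comparator_dalys - strategy_dalys
}

#' Net monetary benefit
#'
#' `NMB = WTP x effectiveness - cost`.
#'
#' @param wtp Willingness-to-pay threshold, I$ per DALY averted.
#' @param effect Effectiveness (DALYs averted).
#' @param cost Lifetime cost, I$.
#' @return NMB in I$.
#' @export
nmb <- function(wtp, effect, cost) {
  wtp * effect - cost
}

#' Efficiency frontier, dominance and ICERs
#'
#' Labels each strategy `on_frontier`, `strongly_dominated` (another
#' strategy costs no more and is at least as effective, strictly better in
#' one) or `extendedly_dominated` (its incremental ICER exceeds that of a
#' more effective strategy), and computes pairwise ICERs along the frontier
#' sorted by effectiveness. Ties at identical effectiveness keep the
#' cheaper strategy; exact (cost, effect) duplicates are both kept and
#' flagged `equivalent`.
#'
#' @param results Data frame with columns `strategy`, `cost`, `effect`.
#' @return The input with added columns `dominance`, `icer`, `equivalent`.
#'   The ICER of the cheapest frontier strategy is `NA`.
#' @export
frontier_and_icers <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("strategy", "cost", "effect") %in% names(results)))
  if (anyDuplicated(results$strategy))
    stop("duplicate strategy names", call. = FALSE)
  if (nrow(results) < 2)
    stop("need at least two strategies (including the comparator)", call. = FALSE)
  n <- nrow(results)
  cost <- results$cost
  eff <- results$effect

  equivalent <- rep(FALSE, n)
  strong <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dup <- which(cost == cost[i] & eff == eff[i])
    if (length(dup) > 1) equivalent[i] <- TRUE
    dom <- any((cost <= cost[i] & eff >= eff[i] &
                  (cost < cost[i] | eff > eff[i])))
    strong[i] <- dom
  }

  cand <- which(!strong)
  # representative per duplicate group to keep the frontier a function of effect
  if (any(equivalent[cand])) {
    keep <- !duplicated(data.frame(cost, eff)[cand, ])
    cand_rep <- cand[keep]
  } else cand_rep <- cand
  ord <- cand_rep[order(eff[cand_rep], cost[cand_rep])]

  ext <- logical(n)
  repeat {
    if (length(ord) <= 2) break
    icers <- diff(cost[ord]) / diff(eff[ord])
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    drop_i <- ord[bad[1] + 1L]           # middle point of the first violation
    ext[drop_i] <- TRUE
    ord <- setdiff(ord, drop_i)
  }

  dominance <- rep("on_frontier", n)
  dominance[ext] <- "extendedly_dominated"
  dominance[strong] <- "strongly_dominated"

  icer <- rep(NA_real_, n)
  if (length(ord) >= 2)
    icer[ord[-1]] <- diff(cost[ord]) / diff(eff[ord])
  # duplicates share their representative's labels
  for (i in which(equivalent)) {
    rep_i <- which(cost == cost[i] & eff == eff[i])[1]
    dominance[i] <- dominance[rep_i]
    icer[i] <- icer[rep_i]
  }

  out <- results
  out$dominance <- dominance
  out$icer <- icer
  out$equivalent <- equivalent
  out
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' The strategy maximizing net monetary benefit; equivalently (a property
#' verified in the test suite) the most effective frontier strategy whose
#' incremental ICER does not exceed the threshold. Ties go to the cheaper
#' strategy.
#'
#' @param results Data frame with columns `strategy`, `cost`, `effect`.
#' @param wtp Willingness-to-pay threshold, I$ per DALY averted.
#' @return Strategy name.
#' @export
select_optimal <- function(results, wtp) {
  stopifnot(nrow(results) >= 1)
  effect <- results$effect %||% results$dalys_averted
  b <- nmb(wtp, effect, results$cost)
  best <- which(b == max(b))
  if (length(best) > 1) best <- best[which.min(results$cost[best])]
  results$strategy[best]
}

#' Full base-case cost-effectiveness analysis
#'
#' Runs the cohort engine for every strategy, accrues discounted societal
#' costs and DALYs, computes DALYs averted and undiscounted overall
#' survival against the no-chemotherapy comparator, and annotates the
#' efficiency frontier, ICERs and net monetary benefit.
#'
#' @param params A `cea_parameters` object.
#' @param strategies Named list of `cea_strategy` (must include
#'   `NO_CHEMO`); default [default_strategies()].
#' @param wtp Willingness-to-pay threshold (default `params$wtp`).
#' @return A `cea_result` data frame with columns `strategy`, `cost`,
#'   `dalys`, `dalys_averted`, `os_years`, `dominance`, `icer`, `nmb`;
#'   attributes `wtp` and `optimal`.
#' @export
run_cea <- function(params, strategies = default_strategies(), wtp = params$wtp) {
  stopifnot("NO_CHEMO" %in% names(strategies))
  per <- lapply(strategies, function(s) {
    tr <- run_cohort(s, params)
    list(cost = accrue_costs(tr, s, params),
         dalys = compute_dalys(tr, params$disability_weights, s, params),
         os = overall_survival_years(tr))
  })
  dalys0 <- per$NO_CHEMO$dalys
  res <- data.frame(
    strategy = names(strategies),
    cost = vapply(per, `[[`, numeric(1), "cost"),
    dalys = vapply(per, `[[`, numeric(1), "dalys"),
    os_years = vapply(per, `[[`, numeric(1), "os"),
    row.names = NULL
  )
  res$effect <- dalys_averted(res$dalys, dalys0)
  res <- frontier_and_icers(res)
  res$nmb <- nmb(wtp, res$effect, res$cost)
  names(res)[names(res) == "effect"] <- "dalys_averted"
  res <- res[, c("strategy", "cost", "dalys", "dalys_averted", "os_years",
                 "dominance", "icer", "nmb", "equivalent")]
  attr(res, "wtp") <- wtp
  attr(res, "optimal") <- res$strategy[which.max(res$nmb)]
  class(res) <- c("cea_result", class(res))
  res
}
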