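# Synthetic inputs: statistically plausible parameter sets emulating the
# model's input tables (recurrence curves, post-recurrence mortality,
# life table, costs, disability weights), plus an individual-level
# microsimulation oracle used to validate the cohort engine.

# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default synthetic scenario
#'
#' Defines the generating process for a complete set of model inputs. The
#' recurrence process is Weibull-like with a gently decreasing hazard
#' (shape 0.9) and per-strategy scales chosen so 5-year recurrence-free
#' survival is about 45% without chemotherapy, 55-57% for single-agent
#' fluoropyrimidines, and 62-64.5% for oxaliplatin doublets, with 6-month
#' FOLFOX slightly better than 3-month FOLFOX and 3-month CAPOX marginally
#' better than 6-month CAPOX. These orderings are synthetic,
#' trial-shaped defaults, not transcriptions of any published curve.
#' Post-recurrence monthly colon-cancer mortality starts higher for earlier
#' recurrences and decays with time already survived in recurrence. The
#' background life table grows geometrically and is forced to probability 1
#' at age 85. Cost magnitudes mimic public-sector input tables in
#' international dollars, including the infusional administration burden
#' (port-a-cath/pump) for FOLFOX.
#'
#' @param seed Integer seed recorded in the scenario.
#' @param start_age Cohort entry age (horizon is `12 * (85 - start_age)`).
#' @param tunnel_depth Months-in-recurrence tunnel depth.
#' @return Object of class `cea_scenario` (a list of generating settings).
#' @export
synthetic_scenario <- function(seed = 1L, start_age = 60, tunnel_depth = 60) {
  dfs5 <- c(NO_CHEMO = 0.45, FULV_6MO = 0.55, CAPECITABINE_6MO = 0.57,
            FOLFOX_3MO = 0.62, CAPOX_6MO = 0.63, CAPOX_3MO = 0.635,
            FOLFOX_6MO = 0.645)
  shape <- 0.9
  hazard <- lapply(dfs5, function(s) {
    list(family = "weibull", shape = shape,
         lambda = (-log(s))^(1 / shape) / 60)
  })

  trae_tab <- function(prob) {
    data.frame(event = TRAE_NAMES,
               probability = prob,
               cost = c(650, 420, 180, 220, 90, 60),
               weight = c(0.15, 0.20, 0.10, 0.12, 0.10, 0.07),
               duration_months = c(0.5, 0.5, 0.25, 6, 1, 1))
  }
  trae_adjuvant <- list(
    NO_CHEMO         = trae_tab(rep(0, 6)),
    FULV_6MO         = trae_tab(c(0.14, 0.12, 0.06, 0.005, 0.02, 0.04)),
    CAPECITABINE_6MO = trae_tab(c(0.02, 0.10, 0.04, 0.005, 0.12, 0.03)),
    FOLFOX_3MO       = trae_tab(c(0.10, 0.08, 0.05, 0.03, 0.02, 0.04)),
    FOLFOX_6MO       = trae_tab(c(0.12, 0.09, 0.05, 0.12, 0.02, 0.04)),
    CAPOX_3MO        = trae_tab(c(0.05, 0.09, 0.05, 0.03, 0.05, 0.04)),
    CAPOX_6MO        = trae_tab(c(0.06, 0.11, 0.05, 0.09, 0.07, 0.04))
  )
  trae_metastatic <- list(
    line1 = trae_tab(c(0.12, 0.10, 0.08, 0.08, 0.04, 0.08)),
    line2 = trae_tab(c(0.10, 0.08, 0.07, 0.05, 0.03, 0.10))
  )

  adj_cost <- function(drug, personnel, administration, antiemetics, bloodwork) {
    c(drug = drug, personnel = personnel, administration = administration,
      antiemetics = antiemetics, bloodwork = bloodwork)
  }
  costs <- list(
    adjuvant = list(
      NO_CHEMO         = adj_cost(0, 0, 0, 0, 0),
      FULV_6MO         = adj_cost(90, 110, 65, 10, 25),
      CAPECITABINE_6MO = adj_cost(160, 30, 12, 8, 20),
      FOLFOX_3MO       = adj_cost(380, 95, 2416.33 / 6, 18, 25),
      FOLFOX_6MO       = adj_cost(380, 95, 2416.33 / 6, 18, 25),
      CAPOX_3MO        = adj_cost(420, 60, 55, 18, 25),
      CAPOX_6MO        = adj_cost(420, 60, 55, 18, 25)
    ),
    surveillance_monthly = 28,
    surveillance_visits_per_month = 1 / 3,
    metastatic = list(line1_monthly = 1600, line2_monthly = 1200,
                      bsc_monthly = 180, visits_per_month = 1),
    hepatectomy = 4200,
    indirect = list(transport_round_trip = 6.03, hourly_wage = 2.52,
                    hours_per_visit = 8, persons = 2)
  )

  structure(
    list(seed = as.integer(seed),
         start_age = start_age,
         tunnel_depth = as.integer(tunnel_depth),
         cure_month = 96L,
         hazard = hazard,
         crc_death = list(base = c(EARLY = 0.05, MID = 0.042, LATE = 0.034),
                          decay = 0.985, floor = 0.012),
         life_table = list(base = 0.012, growth = 1.09),
         disability_weights = list(disease_free = 0.04, recurrence = 0.45,
                                   hepatectomy = 0.32, hepatectomy_months = 1),
         costs = costs,
         trae = list(adjuvant = trae_adjuvant, metastatic = trae_metastatic),
         risk_multipliers = c(low = 0.65, high = 1.5),
         psa = list(cv = 0.2)),
    class = "cea_scenario"
  )
}

# survival function of a scenario hazard model
hazard_survival <- function(hz) {
  switch(hz$family,
         exponential = function(t) exp(-hz$lambda * t),
         weibull = function(t) exp(-(hz$lambda * t)^hz$shape),
         stop("unknown hazard family '", hz$family, "'", call. = FALSE))
}

#' Generate a complete parameter set from a scenario
#'
#' Converts the scenario's closed-form recurrence hazards into monthly
#' probability tables (zero beyond the cure month), builds the
#' post-recurrence mortality grid, life table, cost schedules, TRAE
#' profiles and disability weights, and returns a validated
#' [cea_parameters()] object. Deterministic for a given scenario.
#'
#' @param scenario A `cea_scenario` (default [synthetic_scenario()]).
#' @return A validated `cea_parameters` object.
#' @export
generate_parameter_set <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "cea_scenario"))
  horizon <- 12L * (85L - as.integer(scenario$start_age))
  cure <- scenario$cure_month

  recurrence_prob <- lapply(scenario$hazard, function(hz) {
    S <- hazard_survival(hz)
    m <- seq_len(horizon)
    p <- ifelse(m <= cure, 1 - S(m) / S(m - 1), 0)
    pmin(1, pmax(0, p))
  })

  depth <- scenario$tunnel_depth
  k <- seq_len(depth) - 1L
  cd <- t(vapply(scenario$crc_death$base, function(b)
    pmax(scenario$crc_death$floor, b * scenario$crc_death$decay^k),
    numeric(depth)))
  rownames(cd) <- RECURRENCE_STRATA

  lt <- generate_life_table(scenario$life_table$base, scenario$life_table$growth,
                            start_age = scenario$start_age)

  cea_parameters(
    start_age = scenario$start_age,
    horizon_months = horizon,
    cure_month = cure,
    tunnel_depth = depth,
    recurrence_prob = recurrence_prob,
    crc_death_prob = cd,
    background_mortality = lt,
    disability_weights = scenario$disability_weights,
    costs = scenario$costs,
    trae = scenario$trae,
    risk_multipliers = scenario$risk_multipliers,
    psa = scenario$psa
  )
}

#' Generate Kaplan-Meier-style survival points
#'
#' In noiseless mode returns the exact survival function of the hazard
#' model at the evaluation times; in sampled mode simulates `n_at_risk`
#' event times (inverse-transform, no censoring) and returns the
#' product-limit estimate (via [survival::survfit()]) evaluated at the same
#' times. Stands in for digitized trial curves.
#'
#' @param hazard List with `family` (`"exponential"` or `"weibull"`),
#'   `lambda` (monthly rate scale) and, for Weibull, `shape`.
#' @param times Evaluation times in months, increasing from 0.
#' @param n_at_risk If non-`NULL`, sample size for the empirical mode.
#' @param seed RNG seed for the sampled mode.
#' @param label,source Passed to [km_curve()].
#' @return A [km_curve()].
#' @export
generate_km_points <- function(hazard, times, n_at_risk = NULL, seed = 1L,
                               label = "", source = "synthetic") {
  stopifnot(times[1] == 0, all(diff(times) > 0))
  S <- hazard_survival(hazard)
  if (is.null(n_at_risk)) {
    return(km_curve(times, S(times), label = label, source = source))
  }
  ev <- with_seed(seed, {
    u <- stats::runif(n_at_risk)
    switch(hazard$family,
           exponential = -log(u) / hazard$lambda,
           weibull = (-log(u))^(1 / hazard$shape) / hazard$lambda)
  })
  fit <- survival::survfit(survival::Surv(ev, rep(1, n_at_risk)) ~ 1)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  surv <- step(times)
  surv[1] <- 1
  surv <- cummin(pmin(1, pmax(0, surv)))
  km_curve(times, surv, label = label, source = source)
}

#' Generate a geometric-growth life table
#'
#' Annual background (non-cancer) mortality probability
#' `min(1, base * growth^(age - start_age))` for ages below 85 and exactly 1
#' at 85, emulating the shape of a high-mortality national life table over
#' the modelled ages.
#'
#' @param base_annual_prob Annual probability at `start_age` (> 0).
#' @param growth_per_year Geometric growth factor (>= 1).
#' @param start_age,end_age Age range (default 60-85).
#' @return Data frame with columns `age`, `annual_probability`.
#' @export
generate_life_table <- function(base_annual_prob, growth_per_year,
                                start_age = 60, end_age = 85) {
  stopifnot(base_annual_prob > 0, growth_per_year >= 1, end_age == 85)
  age <- start_age:end_age
  p <- pmin(1, base_annual_prob * growth_per_year^(age - start_age))
  p[age == 85] <- 1
  data.frame(age = age, annual_probability = p)
}

#' Random synthetic scenario (for property tests)
#'
#' Draws a perturbed variant of the default scenario: hazard scales,
#' post-recurrence mortality bases, life-table slope, cost magnitudes and
#' disability weights are jittered within plausible bounds. Used to
#' exercise engine invariants across many parameter sets.
#'
#' @param seed Integer seed.
#' @param start_age,tunnel_depth Passed to [synthetic_scenario()].
#' @return A `cea_scenario`.
#' @export
random_scenario <- function(seed, start_age = 60, tunnel_depth = 60) {
  sc <- synthetic_scenario(seed = seed, start_age = start_age,
                           tunnel_depth = tunnel_depth)
  with_seed(seed, {
    for (s in names(sc$hazard)) {
      sc$hazard[[s]]$lambda <- sc$hazard[[s]]$lambda * stats::runif(1, 0.7, 1.4)
      sc$hazard[[s]]$shape <- stats::runif(1, 0.8, 1.1)
    }
    sc$crc_death$base <- pmin(0.3, sc$crc_death$base * stats::runif(3, 0.7, 1.5))
    sc$crc_death$decay <- stats::runif(1, 0.97, 0.999)
    sc$life_table$base <- stats::runif(1, 0.01, 0.03)
    sc$life_table$growth <- stats::runif(1, 1.05, 1.11)
    sc$disability_weights$recurrence <- stats::runif(1, 0.25, 0.6)
    sc$disability_weights$disease_free <- stats::runif(1, 0, 0.08)
    sc$costs$hepatectomy <- sc$costs$hepatectomy * stats::runif(1, 0.5, 2)
    sc$costs$metastatic$line1_monthly <-
      sc$costs$metastatic$line1_monthly * stats::runif(1, 0.5, 2)
    for (s in names(sc$costs$adjuvant))
      sc$costs$adjuvant[[s]] <- sc$costs$adjuvant[[s]] * stats::runif(1, 0.6, 1.6)
    sc
  })
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` independent monthly trajectories under the
#' same transition probabilities and accrual rules as the cohort engine and
#' returns Monte Carlo estimates of mean discounted cost, mean discounted
#' DALYs, mean undiscounted overall survival and state occupancies, with
#' standard errors. Individuals are exchangeable, so the simulation tracks
#' exact per-state counts (conditional-binomial decomposition of the
#' multinomial transition draw); transition probabilities are recomputed
#' inline from the parameters rather than taken from the cohort engine.
#' Standard errors for cost/DALYs/OS come from `n_batches` independent
#' batch means; occupancy standard errors are binomial.
#'
#' @param strategy A `cea_strategy`.
#' @param params A `cea_parameters`.
#' @param n_individuals Total simulated individuals (split across batches).
#' @param seed RNG seed.
#' @param n_batches Number of independent batches (default 8).
#' @return List with elements `mean_cost`, `se_cost`, `mean_dalys`,
#'   `se_dalys`, `mean_os`, `se_os`, `occupancy` (pooled fraction matrix,
#'   cycles x states), `occupancy_se`, `n`, `n_batches`.
#' @export
microsim_oracle <- function(strategy, params, n_individuals, seed = 1L,
                            n_batches = 8L) {
  stopifnot(n_individuals >= n_batches, n_batches >= 2)
  H <- params$horizon_months
  depth <- params$tunnel_depth
  space <- build_state_space(depth, H)
  S <- space$n_states
  sizes <- rep(n_individuals %/% n_batches, n_batches)
  sizes[seq_len(n_individuals %% n_batches)] <- sizes[1] + 1L

  cd <- params$crc_death_prob
  p_rec_vec <- params$recurrence_prob[[strategy$name]]
  rec_idx_flat <- as.vector(t(space$idx_rec))      # [stratum, k] row-major

  sim_batch <- function(nb) {
    occ <- matrix(0L, nrow = H + 1L, ncol = S,
                  dimnames = list(cycle = 0:H, state = space$states))
    flux <- matrix(0, nrow = H + 1L, ncol = S,
                   dimnames = dimnames(occ))
    df_n <- nb
    R <- matrix(0L, nrow = 3L, ncol = depth)
    d_crc <- 0L
    d_oth <- 0L
    occ[1L, space$idx_df] <- nb
    flux[1L, space$idx_df] <- nb

    for (m in seq_len(H)) {
      q <- background_monthly_prob(params, m)
      if (q >= 1 - 1e-12) {
        alive <- df_n + sum(R)
        d_oth <- d_oth + alive
        flux[m + 1L, space$idx_death_other] <- alive
        df_n <- 0L
        R[] <- 0L
      } else {
        # disease-free exits: recurrence vs background death, rate-apportioned
        p_rec <- if (m > params$cure_month) 0 else p_rec_vec[m]
        exit <- 1 - (1 - p_rec) * (1 - q)
        to_rec <- exit * rate_share(p_rec, q)
        to_oth <- exit - to_rec
        n_rec <- stats::rbinom(1L, df_n, to_rec)
        n_oth <- stats::rbinom(1L, df_n - n_rec,
                               if (to_rec < 1) to_oth / (1 - to_rec) else 0)
        df_n <- df_n - n_rec - n_oth

        # recurrence-state exits, vectorised over the 3 x depth grid
        exit_R <- 1 - (1 - cd) * (1 - q)
        toC <- exit_R * rate_share(cd, q)
        toO <- exit_R - toC
        cnt <- as.vector(R)
        dC <- stats::rbinom(length(cnt), cnt, as.vector(toC))
        dO <- stats::rbinom(length(cnt), cnt - dC,
                            ifelse(as.vector(toC) < 1,
                                   as.vector(toO) / (1 - as.vector(toC)), 0))
        surv <- matrix(cnt - dC - dO, nrow = 3L)
        R_new <- matrix(0L, nrow = 3L, ncol = depth)
        if (depth > 1L) {
          R_new[, 2:depth] <- surv[, 1:(depth - 1L)]
          R_new[, depth] <- R_new[, depth] + surv[, depth]
        } else {
          R_new[, 1L] <- surv[, 1L]
        }
        si <- match(recurrence_stratum(m), RECURRENCE_STRATA)
        R_new[si, 1L] <- R_new[si, 1L] + n_rec
        flux[m + 1L, space$idx_rec[si, 1L]] <- n_rec
        R <- R_new
        d_crc <- d_crc + sum(dC)
        d_oth <- d_oth + sum(dO) + n_oth
        flux[m + 1L, space$idx_death_crc] <- sum(dC)
        flux[m + 1L, space$idx_death_other] <- sum(dO) + n_oth
      }
      occ[m + 1L, space$idx_df] <- df_n
      occ[m + 1L, rec_idx_flat] <- as.vector(t(R))
      occ[m + 1L, space$idx_death_crc] <- d_crc
      occ[m + 1L, space$idx_death_other] <- d_oth
    }
    trace <- structure(
      list(occupancy = occ / nb, entry_flux = flux / nb,
           strategy = strategy$name, space = space, horizon = H),
      class = "cohort_trace")
    list(cost = accrue_costs(trace, strategy, params),
         dalys = compute_dalys(trace, params$disability_weights, strategy, params),
         os = overall_survival_years(trace),
         occ_counts = occ)
  }

  batches <- with_seed(seed, lapply(sizes, sim_batch))

  est <- function(field) {
    v <- vapply(batches, `[[`, numeric(1), field)
    wm <- sum(v * sizes) / sum(sizes)
    list(mean = wm, se = stats::sd(v) / sqrt(n_batches))
  }
  cost <- est("cost"); dalys <- est("dalys"); os <- est("os")
  occ_tot <- Reduce(`+`, lapply(batches, `[[`, "occ_counts"))
  occ_frac <- occ_tot / n_individuals
  occ_se <- sqrt(occ_frac * (1 - occ_frac) / n_individuals)

  list(mean_cost = cost$mean, se_cost = cost$se,
       mean_dalys = dalys$mean, se_dalys = dalys$se,
       mean_os = os$mean, se_os = os$se,
       occupancy = occ_frac, occupancy_se = occ_se,
       n = n_individuals, n_batches = n_batches)
}
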