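# ParameterSet: the single container for every numeric model input.

RECURRENCE_STRATA <- c("EARLY", "MID", "LATE")

TRAE_NAMES <- c("neutropenia", "diarrhea", "nausea_vomiting",
                "peripheral_neuropathy", "hand_foot_syndrome", "fatigue")

#' Construct a model parameter set
#'
#' Bundles every numeric input of the cohort model: the time axis, the cure
#' assumption, per-strategy monthly recurrence probabilities, post-recurrence
#' colon-cancer mortality indexed by recurrence stratum and months spent in
#' recurrence, an age-indexed background life table, cost schedules,
#' disability weights, and optional probabilistic-sensitivity settings.
#'
#' @param start_age Cohort entry age in years.
#' @param horizon_months Model horizon in 1-month cycles; must equal
#'   `12 * (85 - start_age)` so the cohort ages out exactly at 85.
#' @param cure_month Month after which disease-free patients are considered
#'   cured: recurrence probabilities beyond it must be zero.
#' @param discount_rate_annual Annual discount rate applied to costs and
#'   health outcomes alike.
#' @param tunnel_depth Number of months-in-recurrence tunnel states per
#'   stratum; post-recurrence mortality beyond the cap reuses the deepest
#'   entry.
#' @param recurrence_prob Named list, one numeric vector of length
#'   `horizon_months` per strategy: probability of recurrence during each
#'   model month for a patient disease-free at its start.
#' @param crc_death_prob Numeric matrix `3 x tunnel_depth` (rows
#'   `EARLY`/`MID`/`LATE`): monthly probability of colon-cancer death by
#'   recurrence stratum and months already spent in recurrence.
#' @param background_mortality Data frame with columns `age` and
#'   `annual_probability`, covering `start_age:85` with probability 1 at 85.
#' @param liver_only_fraction Fraction of recurrences that are liver-only.
#' @param hepatectomy_fraction_of_liver_only Fraction of liver-only
#'   recurrences undergoing curative-intent hepatectomy.
#' @param line1_months,line2_months Duration (months) of first- and
#'   second-line palliative chemotherapy after recurrence; best supportive
#'   care thereafter.
#' @param disability_weights Named list of weights in `[0, 1]` on the scale
#'   where 0 is no disability and 1 is death from colon cancer: elements
#'   `disease_free`, `recurrence`, `hepatectomy` (one-time surgical
#'   disability weight) and `hepatectomy_months` (its duration).
#' @param costs Cost schedule; see [synthetic_scenario()] for the layout
#'   (per-strategy adjuvant component vectors, surveillance, metastatic
#'   lines, hepatectomy, indirect-cost constants). All amounts in
#'   international dollars (I$).
#' @param trae Treatment-related adverse-event profiles: `$adjuvant` is a
#'   named list (per strategy) of data frames with columns `event`,
#'   `probability`, `cost`, `weight`, `duration_months` (probabilities per
#'   adjuvant course); `$metastatic` is a list with entries `line1` and
#'   `line2` in the same layout (probabilities per treatment line).
#' @param wtp Willingness-to-pay threshold, I$ per DALY averted.
#' @param risk_multipliers Named numeric `c(low = , high = )`: hazard
#'   multipliers applied to recurrence probabilities in the risk-stratified
#'   scenario.
#' @param psa Optional list of PSA distribution settings (see
#'   [draw_parameter_set()]); element `cv` is the default coefficient of
#'   variation.
#' @param validate Check invariants before returning.
#'
#' @return An object of class `cea_parameters`.
#' @export
cea_parameters <- function(start_age = 60,
                           horizon_months = 300,
                           cure_month = 96,
                           discount_rate_annual = 0.05,
                           tunnel_depth = 60,
                           recurrence_prob,
                           crc_death_prob,
                           background_mortality,
                           liver_only_fraction = 1 / 3,
                           hepatectomy_fraction_of_liver_only = 1 / 3,
                           line1_months = 6,
                           line2_months = 6,
                           disability_weights,
                           costs,
                           trae,
                           wtp = 13006.56,
                           risk_multipliers = c(low = 0.65, high = 1.5),
                           psa = list(cv = 0.2),
                           validate = TRUE) {
  params <- structure(
    list(
      schema_version = "colcea/1",
      start_age = start_age,
      horizon_months = as.integer(horizon_months),
      cycle_months = 1L,
      cure_month = as.integer(cure_month),
      discount_rate_annual = discount_rate_annual,
      tunnel_depth = as.integer(tunnel_depth),
      recurrence_prob = recurrence_prob,
      crc_death_prob = crc_death_prob,
      background_mortality = background_mortality,
      liver_only_fraction = liver_only_fraction,
      hepatectomy_fraction_of_liver_only = hepatectomy_fraction_of_liver_only,
      line1_months = as.integer(line1_months),
      line2_months = as.integer(line2_months),
      disability_weights = disability_weights,
      costs = costs,
      trae = trae,
      wtp = wtp,
      risk_multipliers = risk_multipliers,
      psa = psa
    ),
    class = "cea_parameters"
  )
  if (validate) validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a [cea_parameters()] object:
#' probabilities and disability weights in `[0, 1]`, non-negative costs,
#' the life table covering `start_age:85` and reaching probability 1 at 85,
#' recurrence probabilities zero beyond the cure month, and the horizon
#' spanning exactly to age 85.
#'
#' @param params A `cea_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending entry.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  fail <- function(...) stop("invalid parameter set: ", sprintf(...), call. = FALSE)

  p <- params
  if (p$horizon_months != 12L * (85L - p$start_age))
    fail("horizon_months must equal 12*(85 - start_age) = %d, got %d",
         12L * (85L - p$start_age), p$horizon_months)
  if (p$cure_month < 1L || p$cure_month > p$horizon_months)
    fail("cure_month out of range")
  if (p$tunnel_depth < 1L) fail("tunnel_depth must be >= 1")
  if (p$discount_rate_annual < 0) fail("discount_rate_annual must be >= 0")

  lt <- p$background_mortality
  if (!all(c("age", "annual_probability") %in% names(lt)))
    fail("background_mortality needs columns age, annual_probability")
  need_ages <- p$start_age:85
  if (!all(need_ages %in% lt$age))
    fail("background_mortality must cover ages %d-85", p$start_age)
  q <- lt$annual_probability[match(need_ages, lt$age)]
  if (any(q < 0 | q > 1)) fail("background_mortality probabilities outside [0,1]")
  if (abs(q[length(q)] - 1) > 1e-12)
    fail("background_mortality at age 85 must be 1.0")

  if (!is.list(p$recurrence_prob) || is.null(names(p$recurrence_prob)))
    fail("recurrence_prob must be a named list per strategy")
  for (s in names(p$recurrence_prob)) {
    r <- p$recurrence_prob[[s]]
    if (length(r) != p$horizon_months)
      fail("recurrence_prob[%s] must have length horizon_months", s)
    if (any(r < 0 | r > 1)) fail("recurrence_prob[%s] outside [0,1]", s)
    if (p$cure_month < p$horizon_months &&
        any(r[(p$cure_month + 1L):p$horizon_months] != 0))
      fail("recurrence_prob[%s] must be 0 beyond cure_month %d", s, p$cure_month)
  }

  cd <- p$crc_death_prob
  if (!is.matrix(cd) || nrow(cd) != 3L || !identical(rownames(cd), RECURRENCE_STRATA))
    fail("crc_death_prob must be a 3-row matrix with rows EARLY, MID, LATE")
  if (ncol(cd) != p$tunnel_depth)
    fail("crc_death_prob must have tunnel_depth = %d columns", p$tunnel_depth)
  if (any(cd < 0 | cd > 1)) fail("crc_death_prob outside [0,1]")

  frac_ok <- function(x) length(x) == 1 && x >= 0 && x <= 1
  if (!frac_ok(p$liver_only_fraction)) fail("liver_only_fraction outside [0,1]")
  if (!frac_ok(p$hepatectomy_fraction_of_liver_only))
    fail("hepatectomy_fraction_of_liver_only outside [0,1]")

  dw <- p$disability_weights
  for (nm in c("disease_free", "recurrence", "hepatectomy")) {
    if (is.null(dw[[nm]])) fail("disability_weights$%s missing", nm)
    if (dw[[nm]] < 0 || dw[[nm]] > 1) fail("disability_weights$%s outside [0,1]", nm)
  }
  if (is.null(dw$hepatectomy_months) || dw$hepatectomy_months < 0)
    fail("disability_weights$hepatectomy_months missing or negative")

  co <- p$costs
  for (nm in c("adjuvant", "surveillance_monthly", "surveillance_visits_per_month",
               "metastatic", "hepatectomy", "indirect")) {
    if (is.null(co[[nm]])) fail("costs$%s missing", nm)
  }
  for (s in names(co$adjuvant)) {
    if (any(co$adjuvant[[s]] < 0)) fail("costs$adjuvant$%s has negative component", s)
  }
  if (any(unlist(co$metastatic) < 0)) fail("costs$metastatic negative")
  if (co$hepatectomy < 0) fail("costs$hepatectomy negative")
  ind <- co$indirect
  for (nm in c("transport_round_trip", "hourly_wage", "hours_per_visit", "persons")) {
    if (is.null(ind[[nm]]) || ind[[nm]] < 0) fail("costs$indirect$%s missing or negative", nm)
  }

  check_trae <- function(tab, where) {
    if (!is.data.frame(tab) ||
        !all(c("event", "probability", "cost", "weight", "duration_months") %in% names(tab)))
      fail("trae table %s malformed", where)
    if (any(tab$probability < 0 | tab$probability > 1))
      fail("trae %s probability outside [0,1]", where)
    if (any(tab$weight < 0 | tab$weight > 1)) fail("trae %s weight outside [0,1]", where)
    if (any(tab$cost < 0) || any(tab$duration_months < 0))
      fail("trae %s negative cost or duration", where)
  }
  for (s in names(p$trae$adjuvant)) check_trae(p$trae$adjuvant[[s]], paste0("adjuvant$", s))
  for (l in names(p$trae$metastatic)) check_trae(p$trae$metastatic[[l]], paste0("metastatic$", l))

  if (p$wtp <= 0) fail("wtp must be positive")
  invisible(params)
}

#' Read or replace a parameter by dotted path
#'
#' Addresses entries of a nested parameter list with a dotted string, e.g.
#' `"costs.hepatectomy"` or `"trae.adjuvant.FOLFOX_6MO"`. Used by the
#' deterministic sensitivity analysis to perturb one input at a time.
#'
#' @param params A `cea_parameters` object (or plain nested list).
#' @param path Dotted character path.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the addressed entry; `param_set` returns the
#'   modified object.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- params
  for (k in keys) {
    if (is.null(out[[k]])) stop("no parameter at path '", path, "'", call. = FALSE)
    out <- out[[k]]
  }
  out
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  param_get(params, path)  # errors early if the path is absent
  rec <- function(x, keys) {
    if (length(keys) == 1L) {
      x[[keys]] <- value
      return(x)
    }
    x[[keys[1L]]] <- rec(x[[keys[1L]]], keys[-1L])
    x
  }
  out <- rec(unclass(params), keys)
  class(out) <- class(params)
  out
}

#' Convert an annual probability to a monthly probability
#'
#' Assumes a constant hazard within the year: `1 - (1 - p)^(1/12)`.
#'
#' @param p_annual Annual probability in `[0, 1]`.
#' @return Monthly probability.
#' @export
annual_to_monthly_prob <- function(p_annual) {
  stopifnot(all(p_annual >= 0 & p_annual <= 1))
  1 - (1 - p_annual)^(1 / 12)
}

# Monthly background-mortality probability for model month m (1-based, the
# month being completed). Age indexing floor(start_age + m/12) makes month
# 300 hit age 85, whose annual probability 1 removes all survivors.
background_monthly_prob <- function(params, month) {
  age <- floor(params$start_age + month / 12)
  lt <- params$background_mortality
  q_annual <- lt$annual_probability[match(age, lt$age)]
  if (anyNA(q_annual)) stop("life table missing age ", paste(age[is.na(q_annual)], collapse = ", "))
  annual_to_monthly_prob(q_annual)
}
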