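# Configuration and table I/O, plus scenario orchestration.

params_to_list <- function(params) {
  p <- unclass(params)
  p$crc_death_prob <- as.list(as.data.frame(t(p$crc_death_prob)))
  p$background_mortality <- as.list(p$background_mortality)
  p$risk_multipliers <- as.list(p$risk_multipliers)
  p$trae$adjuvant <- lapply(p$trae$adjuvant, as.list)
  p$trae$metastatic <- lapply(p$trae$metastatic, as.list)
  p$costs$adjuvant <- lapply(p$costs$adjuvant, as.list)
  p
}

list_to_params <- function(x) {
  need <- c("schema_version", "start_age", "horizon_months", "cure_month",
            "recurrence_prob", "crc_death_prob", "background_mortality",
            "disability_weights", "costs", "trae")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("config missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(x$schema_version, "colcea/1"))
    stop("unrecognized schema_version: ", x$schema_version, call. = FALSE)
  cd <- do.call(rbind, x$crc_death_prob[RECURRENCE_STRATA])
  x$costs$adjuvant <- lapply(x$costs$adjuvant, unlist)
  cea_parameters(
    start_age = x$start_age,
    horizon_months = x$horizon_months,
    cure_month = x$cure_month,
    discount_rate_annual = x$discount_rate_annual,
    tunnel_depth = x$tunnel_depth,
    recurrence_prob = lapply(x$recurrence_prob, as.numeric),
    crc_death_prob = cd,
    background_mortality = as.data.frame(x$background_mortality),
    liver_only_fraction = x$liver_only_fraction,
    hepatectomy_fraction_of_liver_only = x$hepatectomy_fraction_of_liver_only,
    line1_months = x$line1_months,
    line2_months = x$line2_months,
    disability_weights = x$disability_weights,
    costs = x$costs,
    trae = list(adjuvant = lapply(x$trae$adjuvant, as.data.frame),
                metastatic = lapply(x$trae$metastatic, as.data.frame)),
    wtp = x$wtp,
    risk_multipliers = unlist(x$risk_multipliers),
    psa = x$psa
  )
}

#' Write or read a parameter configuration
#'
#' Serializes a full parameter set to a versioned YAML file (schema key
#' `colcea/1`) and reads it back with full validation. Numeric precision is
#' preserved to ~15 significant digits.
#'
#' @param params A `cea_parameters` object.
#' @param path File path.
#' @param precision Significant digits written (default 15).
#' @return `read_config` returns a validated `cea_parameters`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(params, path, precision = 15) {
  stopifnot(inherits(params, "cea_parameters"))
  yaml::write_yaml(params_to_list(params), path, precision = precision)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  list_to_params(yaml::read_yaml(path))
}

#' Read/write digitized Kaplan-Meier points as CSV
#'
#' Two-column CSV (`time_months`, `survival`).
#'
#' @param path File path.
#' @param curve A [km_curve()].
#' @param label,source Passed to [km_curve()] when reading.
#' @return `read_km_csv` returns a `km_curve`; `write_km_csv` returns
#'   `path` invisibly.
#' @export
read_km_csv <- function(path, label = basename(path), source = path) {
  d <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(d)))
    stop("KM csv needs columns time_months, survival", call. = FALSE)
  km_curve(d$time_months, d$survival, label = label, source = source)
}

#' @rdname read_km_csv
#' @export
write_km_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_months = curve$time, survival = curve$survival),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a life table CSV
#'
#' Two-column CSV (`age`, `annual_probability`).
#'
#' @param path File path.
#' @return Data frame usable as `background_mortality`.
#' @export
read_life_table_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "annual_probability") %in% names(d)))
    stop("life table csv needs columns age, annual_probability", call. = FALSE)
  d[, c("age", "annual_probability")]
}

#' Export a cohort trace as CSV
#'
#' Cycle-by-state occupancy fractions.
#'
#' @param trace A `cohort_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  d <- data.frame(cycle = 0:trace$horizon, trace$occupancy, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Calibrate a monthly recurrence table from digitized points
#'
#' Convenience wrapper chaining [fit_survival_spline()] and
#' [extrapolate_and_cure()].
#'
#' @param curve A [km_curve()].
#' @param trial_end Last month supported by the data (default: last
#'   digitized time).
#' @param cure_month,horizon,tail,smoothing Passed through.
#' @return Monthly probability vector of length `horizon`.
#' @export
calibrate_recurrence <- function(curve, trial_end = max(curve$time),
                                 cure_month = 96, horizon = 300,
                                 tail = "carry-forward-hazard",
                                 smoothing = list(method = "monotone-interp",
                                                  tol = 0.005)) {
  S <- fit_survival_spline(curve, smoothing)
  extrapolate_and_cure(S, trial_end = trial_end, cure_month = cure_month,
                       horizon = horizon, tail = tail)
}

#' Run the base-case or a risk-stratified scenario
#'
#' `"base"` runs all seven strategies. The risk scenarios restrict the
#' comparison to the four oxaliplatin doublets plus the no-chemotherapy
#' comparator and scale every arm's recurrence hazard by the corresponding
#' risk multiplier (`params$risk_multipliers["low"|"high"]`), reflecting
#' recurrence-risk strata (low: T1-3 N1; high: T4 and/or N2). The labels
#' are configuration only; the model consumes risk-specific recurrence
#' probabilities, not staging data.
#'
#' @param params A `cea_parameters`.
#' @param scenario `"base"`, `"low_risk"` or `"high_risk"`.
#' @param wtp WTP threshold (default `params$wtp`).
#' @return A `cea_result` (see [run_cea()]) with attribute `scenario`.
#' @export
run_scenario <- function(params, scenario = c("base", "low_risk", "high_risk"),
                         wtp = params$wtp) {
  scenario <- match.arg(scenario)
  if (scenario == "base") {
    res <- run_cea(params, default_strategies(), wtp)
  } else {
    key <- sub("_risk$", "", scenario)
    mult <- if (key %in% names(params$risk_multipliers))
      params$risk_multipliers[[key]] else NULL
    if (is.null(mult) || is.na(mult))
      stop("missing risk multiplier '", key, "' for scenario ", scenario,
           call. = FALSE)
    arms <- c("NO_CHEMO", OXALIPLATIN_STRATEGIES)
    for (s in arms)
      params$recurrence_prob[[s]] <- 1 - (1 - params$recurrence_prob[[s]])^mult
    res <- run_cea(params, default_strategies(arms), wtp)
  }
  attr(res, "scenario") <- scenario
  res
}
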