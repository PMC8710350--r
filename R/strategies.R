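# Treatment strategies: the six adjuvant regimens plus the surgery-only
# comparator.

STRATEGY_NAMES <- c("NO_CHEMO", "FULV_6MO", "CAPECITABINE_6MO",
                    "FOLFOX_3MO", "FOLFOX_6MO", "CAPOX_3MO", "CAPOX_6MO")

OXALIPLATIN_STRATEGIES <- c("FOLFOX_3MO", "FOLFOX_6MO", "CAPOX_3MO", "CAPOX_6MO")

#' Define a treatment strategy
#'
#' A strategy is a named adjuvant regimen with a duration, a total number of
#' treatment visits over the course (each visit incurs indirect transport and
#' lost-wage costs for the patient and a caregiver), and a flag for
#' infusional delivery (which drives port-a-cath/infusion-pump
#' administration costs in the cost schedule).
#'
#' @param name Strategy identifier; one of
#'   `NO_CHEMO`, `FULV_6MO`, `CAPECITABINE_6MO`, `FOLFOX_3MO`, `FOLFOX_6MO`,
#'   `CAPOX_3MO`, `CAPOX_6MO`.
#' @param adjuvant_duration_months 0, 3 or 6.
#' @param n_treatment_visits Total clinic visits over the adjuvant course.
#' @param is_infusional Whether the regimen is delivered by continuous
#'   infusion.
#' @return An object of class `cea_strategy`.
#' @export
strategy_spec <- function(name, adjuvant_duration_months, n_treatment_visits,
                          is_infusional) {
  name <- match.arg(name, STRATEGY_NAMES)
  stopifnot(adjuvant_duration_months %in% c(0L, 3L, 6L),
            n_treatment_visits >= 0)
  if (name == "NO_CHEMO" && (adjuvant_duration_months != 0 || n_treatment_visits != 0))
    stop("NO_CHEMO must have zero duration and zero visits", call. = FALSE)
  structure(
    list(name = name,
         adjuvant_duration_months = as.integer(adjuvant_duration_months),
         n_treatment_visits = as.integer(n_treatment_visits),
         is_infusional = isTRUE(is_infusional)),
    class = "cea_strategy"
  )
}

#' Default strategy set
#'
#' The seven modelled arms. Visit counts follow routine delivery: oral
#' capecitabine-based regimens need one visit per 3-week cycle while
#' infusional fluorouracil needs five, giving 8 total visits for CAPOX 6MO
#' versus 12 for FOLFOX 6MO, scaled proportionally for the 3-month arms;
#' FU/LV (Mayo) uses 5 visits per monthly cycle.
#'
#' @param names Optional subset of strategy names to return.
#' @return Named list of `cea_strategy` objects.
#' @export
default_strategies <- function(names = STRATEGY_NAMES) {
  all <- list(
    NO_CHEMO         = strategy_spec("NO_CHEMO", 0, 0, FALSE),
    FULV_6MO         = strategy_spec("FULV_6MO", 6, 30, TRUE),
    CAPECITABINE_6MO = strategy_spec("CAPECITABINE_6MO", 6, 6, FALSE),
    FOLFOX_3MO       = strategy_spec("FOLFOX_3MO", 3, 6, TRUE),
    FOLFOX_6MO       = strategy_spec("FOLFOX_6MO", 6, 12, TRUE),
    CAPOX_3MO        = strategy_spec("CAPOX_3MO", 3, 4, FALSE),
    CAPOX_6MO        = strategy_spec("CAPOX_6MO", 6, 8, FALSE)
  )
  names <- match.arg(names, STRATEGY_NAMES, several.ok = TRUE)
  all[names]
}
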