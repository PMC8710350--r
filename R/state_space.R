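# Health-state space: disease-free, duration-stratified recurrence tunnels,
# and two absorbing death states.

#' Enumerate the expanded health-state space
#'
#' The cohort occupies one of: `DiseaseFree`; a recurrence tunnel state
#' `Rec_<STRATUM>_<k>` where the stratum records when the recurrence
#' happened relative to surgery (`EARLY`: months 1-24, `MID`: 25-36,
#' `LATE`: 37+) and `k = 0, 1, ...` counts months already spent in
#' recurrence (capped at `tunnel_depth - 1`, the deepest state
#' self-looping); or the absorbing states `DeathCRC` and `DeathOther`.
#'
#' @param tunnel_depth Number of months-in-recurrence tunnel states per
#'   stratum (>= 1).
#' @param horizon Model horizon in months (>= 1); carried as metadata.
#' @return An object of class `cea_state_space`: a list with the ordered
#'   `states` character vector and index helpers.
#' @export
build_state_space <- function(tunnel_depth, horizon) {
  if (length(tunnel_depth) != 1 || is.na(tunnel_depth) || tunnel_depth < 1)
    stop("tunnel_depth must be a positive integer", call. = FALSE)
  if (length(horizon) != 1 || is.na(horizon) || horizon < 1)
    stop("horizon must be a positive integer", call. = FALSE)
  tunnel_depth <- as.integer(tunnel_depth)
  horizon <- as.integer(horizon)

  rec <- as.vector(t(outer(RECURRENCE_STRATA, seq_len(tunnel_depth) - 1L,
                           function(s, k) sprintf("Rec_%s_%03d", s, k))))
  states <- c("DiseaseFree", rec, "DeathCRC", "DeathOther")
  stopifnot(!anyDuplicated(states))

  idx_rec <- matrix(seq_along(rec) + 1L, nrow = 3L, byrow = TRUE,
                    dimnames = list(RECURRENCE_STRATA, NULL))
  structure(
    list(states = states,
         n_states = length(states),
         tunnel_depth = tunnel_depth,
         horizon = horizon,
         idx_df = 1L,
         idx_rec = idx_rec,           # [stratum, k+1] -> column index
         idx_death_crc = length(states) - 1L,
         idx_death_other = length(states),
         alive = seq_len(length(states) - 2L)),
    class = "cea_state_space"
  )
}

#' Recurrence stratum for a model month
#'
#' Recurrences arising in months 1-24 enter the `EARLY` stratum, months
#' 25-36 `MID`, and later months `LATE`; boundary months belong to the
#' earlier stratum.
#'
#' @param month Model month (1-based).
#' @return One of `"EARLY"`, `"MID"`, `"LATE"`.
#' @export
recurrence_stratum <- function(month) {
  ifelse(month <= 24, "EARLY", ifelse(month <= 36, "MID", "LATE"))
}

# Rate share of cause A among two competing causes with marginal monthly
# probabilities pA, pB. Probability-1 causes carry infinite rates and take
# the whole share (or half each if both are certain). Vectorised.
rate_share <- function(pA, pB) {
  if (length(pA) == 1L && length(pB) == 1L) {
    if (pA >= 1 && pB >= 1) return(0.5)
    if (pA >= 1) return(1)
    if (pB >= 1) return(0)
    rA <- -log1p(-pA)
    rB <- -log1p(-pB)
    return(if (rA + rB > 0) rA / (rA + rB) else 0)
  }
  rA <- -log1p(-pA)
  rB <- -log1p(-pB)
  ifelse(is.infinite(rA) & is.infinite(rB), 0.5,
         ifelse(is.infinite(rA), 1,
                ifelse(is.infinite(rB), 0,
                       ifelse(rA + rB > 0, rA / (rA + rB), 0))))
}

# Competing-risk combination within a cycle: convert marginal monthly
# probabilities to rates, sum, convert back, apportion by rate share.
# Keeps the row stochastic for large marginals. Vectorised over p1/p2.
combine_competing_pair <- function(p1, p2) {
  stay <- (1 - p1) * (1 - p2)
  exit <- 1 - stay
  share1 <- rate_share(p1, p2)
  list(stay = stay, to1 = exit * share1, to2 = exit * (1 - share1))
}

#' One row of the month-specific transition matrix
#'
#' Transition probabilities out of `state` during model month `month` (the
#' 1-based month being completed). From `DiseaseFree` the competing exits
#' are recurrence (probability from the strategy's calibrated monthly table,
#' zero beyond the cure month) and background non-cancer death from the life
#' table at age `floor(start_age + month/12)`; from a recurrence tunnel
#' state they are colon-cancer death (indexed by stratum and months in
#' recurrence) and background death, the survivors advancing one tunnel
#' state. Competing exits are combined on the rate scale so the row stays
#' stochastic. Death rows are identity. When the life table forces the
#' monthly background probability to 1 (age 85), all remaining alive mass
#' moves to `DeathOther`.
#'
#' @param state A state identifier from [build_state_space()].
#' @param month Model month, 1-based, `<= horizon`.
#' @param params A `cea_parameters` object.
#' @param strategy A `cea_strategy` object (selects the recurrence table).
#' @param space Optional pre-built `cea_state_space`.
#' @return Named probability vector over the full state space, summing to 1.
#' @export
transition_row <- function(state, month, params, strategy, space = NULL) {
  if (is.null(space))
    space <- build_state_space(params$tunnel_depth, params$horizon_months)
  if (month < 1 || month > params$horizon_months)
    stop("month outside horizon", call. = FALSE)
  i <- match(state, space$states)
  if (is.na(i)) stop("unknown state '", state, "'", call. = FALSE)

  row <- numeric(space$n_states)
  names(row) <- space$states

  if (i %in% c(space$idx_death_crc, space$idx_death_other)) {
    row[i] <- 1
    return(row)
  }

  q <- background_monthly_prob(params, month)
  terminal <- q >= 1 - 1e-12

  if (i == space$idx_df) {
    p_rec <- params$recurrence_prob[[strategy$name]][month]
    if (month > params$cure_month) p_rec <- 0
    if (p_rec < 0 || p_rec > 1)
      stop("recurrence probability for ", strategy$name, " month ", month,
           " outside [0,1]", call. = FALSE)
    if (terminal) {
      row[space$idx_death_other] <- 1
      return(row)
    }
    cr <- combine_competing_pair(p_rec, q)
    stratum <- recurrence_stratum(month)
    row[space$idx_df] <- cr$stay
    row[space$idx_rec[stratum, 1L]] <- cr$to1
    row[space$idx_death_other] <- cr$to2
    return(row)
  }

  # recurrence tunnel state
  pos <- which(space$idx_rec == i, arr.ind = TRUE)
  stratum <- RECURRENCE_STRATA[pos[1L]]
  k <- pos[2L] - 1L
  if (terminal) {
    row[space$idx_death_other] <- 1
    return(row)
  }
  p_crc <- params$crc_death_prob[stratum, min(k, params$tunnel_depth - 1L) + 1L]
  cr <- combine_competing_pair(p_crc, q)
  k_next <- min(k + 1L, params$tunnel_depth - 1L)
  row[space$idx_rec[stratum, k_next + 1L]] <- cr$stay
  row[space$idx_death_crc] <- cr$to1
  row[space$idx_death_other] <- cr$to2
  row
}
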