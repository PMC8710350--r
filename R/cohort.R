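# Markov cohort engine: deterministic monthly state-transition simulation of
# one strategy under one parameter set.

#' Run the cohort simulation for one strategy
#'
#' Propagates the full cohort (mass 1, starting disease-free) through the
#' monthly transition structure of [transition_row()] for
#' `params$horizon_months` cycles. The engine applies the same vectorised
#' update to every recurrence tunnel state at once; a consistency test in
#' the package verifies that the update equals composing [transition_row()]
#' rows into a transition matrix.
#'
#' @param strategy A `cea_strategy` object.
#' @param params A `cea_parameters` object.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`(horizon+1) x n_states` matrix of cohort fractions, rows = cycles
#'   0..horizon), `entry_flux` (same shape; new mass entering each state at
#'   each cycle, used for one-time costs such as hepatectomy), the
#'   `strategy` name and the `space` used.
#' @export
run_cohort <- function(strategy, params) {
  stopifnot(inherits(strategy, "cea_strategy"), inherits(params, "cea_parameters"))
  H <- params$horizon_months
  depth <- params$tunnel_depth
  space <- build_state_space(depth, H)
  S <- space$n_states

  occ <- matrix(0, nrow = H + 1L, ncol = S,
                dimnames = list(cycle = 0:H, state = space$states))
  flux <- occ
  occ[1L, space$idx_df] <- 1
  flux[1L, space$idx_df] <- 1

  p_rec_vec <- params$recurrence_prob[[strategy$name]]
  if (is.null(p_rec_vec))
    stop("no recurrence probabilities for strategy ", strategy$name, call. = FALSE)
  p_rec_vec[seq_len(H) > params$cure_month] <- 0

  # month-invariant pieces hoisted out of the cycle loop
  q_all <- background_monthly_prob(params, seq_len(H))
  age_all <- floor(params$start_age + seq_len(H) / 12)
  stratum_all <- match(recurrence_stratum(seq_len(H)), RECURRENCE_STRATA)
  rec_flat <- as.vector(t(space$idx_rec))     # state columns, stratum-major
  cdT <- t(params$crc_death_prob)             # [k+1, stratum]
  cr_all <- combine_competing_pair(p_rec_vec, q_all)  # disease-free exits

  df <- 1
  RT <- matrix(0, nrow = depth, ncol = 3L)    # recurrence occupancy [k+1, stratum]
  d_crc <- 0
  d_oth <- 0
  cur_age <- -1L
  stay_R <- toC_R <- toO_R <- NULL
  idx_dc <- space$idx_death_crc
  idx_do <- space$idx_death_other

  for (m in seq_len(H)) {
    q <- q_all[m]

    if (q >= 1 - 1e-12) {
      alive <- df + sum(RT)
      d_oth <- d_oth + alive
      flux[m + 1L, idx_do] <- alive
      df <- 0
      RT[] <- 0
    } else {
      if (age_all[m] != cur_age) {
        # recurrence-state exit probabilities change only when age (hence q) does
        exit <- 1 - (1 - cdT) * (1 - q)
        share <- rate_share(cdT, q)
        toC_R <- exit * share
        toO_R <- exit * (1 - share)
        stay_R <- 1 - exit
        cur_age <- age_all[m]
      }

      new_rec_entry <- df * cr_all$to1[m]
      d_oth_inc <- df * cr_all$to2[m]
      df <- df * cr_all$stay[m]

      dC <- sum(RT * toC_R)
      dO <- sum(RT * toO_R)
      Rs <- RT * stay_R
      # advance one tunnel month; deepest state self-loops
      R_new <- matrix(0, nrow = depth, ncol = 3L)
      if (depth > 1L) {
        R_new[2:depth, ] <- Rs[1:(depth - 1L), , drop = FALSE]
        R_new[depth, ] <- R_new[depth, ] + Rs[depth, ]
        arrivals <- R_new
        arrivals[depth, ] <- R_new[depth, ] - Rs[depth, ]  # self-loop mass is not an entry
      } else {
        R_new[1L, ] <- Rs[1L, ]
        arrivals <- matrix(0, nrow = depth, ncol = 3L)
      }
      si <- stratum_all[m]
      R_new[1L, si] <- R_new[1L, si] + new_rec_entry
      arrivals[1L, si] <- arrivals[1L, si] + new_rec_entry
      RT <- R_new
      d_crc <- d_crc + dC
      d_oth <- d_oth + dO + d_oth_inc

      flux[m + 1L, rec_flat] <- arrivals
      flux[m + 1L, idx_dc] <- dC
      flux[m + 1L, idx_do] <- dO + d_oth_inc
    }

    occ[m + 1L, space$idx_df] <- df
    occ[m + 1L, rec_flat] <- RT
    occ[m + 1L, idx_dc] <- d_crc
    occ[m + 1L, idx_do] <- d_oth
  }

  dev <- max(abs(rowSums(occ) - 1))
  if (dev > 1e-9)
    stop("cohort trace rows deviate from 1 by ", format(dev), call. = FALSE)

  structure(
    list(occupancy = occ, entry_flux = flux,
         strategy = strategy$name, space = space,
         horizon = H),
    class = "cohort_trace"
  )
}

#' Half-cycle accrual weights
#'
#' Trapezoidal (half-cycle-corrected) per-cycle accrual: the weight for
#' cycle `t` is the mean of occupancy at its two boundaries, so summed
#' weights equal the trapezoidal integral of occupancy over the horizon.
#'
#' @param trace A `cohort_trace`.
#' @return A `horizon x n_states` matrix of accrual weights; row `t` covers
#'   model month `t` (cycle boundaries `t-1` and `t`).
#' @export
half_cycle_weights <- function(trace) {
  occ <- trace$occupancy
  H <- trace$horizon
  (occ[1:H, , drop = FALSE] + occ[2:(H + 1L), , drop = FALSE]) / 2
}

#' Undiscounted overall survival in life-years
#'
#' Half-cycle-corrected person-time in the alive states (disease-free plus
#' all recurrence tunnels), in years. No discounting and no disability
#' adjustment.
#'
#' @param trace A `cohort_trace`.
#' @return Mean overall survival in years.
#' @export
overall_survival_years <- function(trace) {
  w <- half_cycle_weights(trace)
  sum(w[, trace$space$alive]) / 12
}

#' Occupancy aggregated to clinical health states
#'
#' Collapses the expanded tunnel enumeration to the model's clinical
#' states: disease-free, the three recurrence strata, and the two death
#' states.
#'
#' @param occ Occupancy matrix (cycles x expanded states).
#' @param space The matching `cea_state_space`.
#' @return Matrix with columns `DiseaseFree`, `Rec_EARLY`, `Rec_MID`,
#'   `Rec_LATE`, `DeathCRC`, `DeathOther`.
#' @export
group_occupancy <- function(occ, space) {
  cbind(
    DiseaseFree = occ[, space$idx_df],
    Rec_EARLY = rowSums(occ[, space$idx_rec["EARLY", ], drop = FALSE]),
    Rec_MID = rowSums(occ[, space$idx_rec["MID", ], drop = FALSE]),
    Rec_LATE = rowSums(occ[, space$idx_rec["LATE", ], drop = FALSE]),
    DeathCRC = occ[, space$idx_death_crc],
    DeathOther = occ[, space$idx_death_other]
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> strategy:", x$strategy,
      "| cycles:", x$horizon,
      "| states:", x$space$n_states, "\n")
  alive <- rowSums(x$occupancy[, x$space$alive, drop = FALSE])
  cat("  alive fraction at months 12/60/120/300:",
      paste(sprintf("%.3f", alive[c(13, 61, 121, x$horizon + 1)]), collapse = " / "),
      "\n")
  invisible(x)
}
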