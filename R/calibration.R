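# Calibration: digitized Kaplan-Meier survival points -> monotone spline
# survival function -> monthly recurrence probabilities with tail
# extrapolation and the cure assumption.

#' Digitized Kaplan-Meier curve
#'
#' Container for digitized survival coordinates (time in months, survival
#' fraction) of a disease-free or recurrence-free survival curve.
#'
#' @param time Numeric vector of months, strictly increasing, starting at 0.
#' @param survival Survival fractions in `[0, 1]`, non-increasing, with
#'   `survival[time == 0] == 1`.
#' @param label Curve label (strategy and endpoint).
#' @param source Free-text provenance.
#' @return Object of class `km_curve`.
#' @export
km_curve <- function(time, survival, label = "", source = "") {
  if (length(time) != length(survival))
    stop("time and survival must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (time[1] != 0 || abs(survival[1] - 1) > 1e-12)
    stop("curve must start at (0, 1)", call. = FALSE)
  if (any(survival < 0 | survival > 1))
    stop("survival values outside [0,1]", call. = FALSE)
  bad <- which(diff(survival) > 1e-12)
  if (length(bad))
    stop("survival increases at time pairs: ",
         paste(sprintf("(%g -> %g)", time[bad], time[bad + 1]), collapse = ", "),
         call. = FALSE)
  structure(list(time = as.numeric(time), survival = as.numeric(survival),
                 label = label, source = source),
            class = "km_curve")
}

#' Fit a monotone survival spline to digitized points
#'
#' Fits on the log-survival scale. The default method is a monotone
#' (Hyman-filtered) cubic interpolating spline, which passes exactly through
#' the digitized points and preserves their monotonicity; method
#' `"smooth"` fits a smoothing spline to log-survival and projects the
#' result onto the non-increasing cone (isotonic regression on a monthly
#' grid) for noisy digitizations. The fitted function is checked against
#' every input point to within `tol`.
#'
#' @param curve A [km_curve()].
#' @param smoothing List: `method` (`"monotone-interp"` or `"smooth"`),
#'   `tol` (maximum allowed absolute deviation from input points, default
#'   0.005 survival units), and for `"smooth"` a `df` passed to
#'   [stats::smooth.spline()].
#' @return Object of class `survival_fn`: callable metadata list whose
#'   `$eval(t)` returns survival at continuous time `t` months. Beyond the
#'   last digitized time the last monthly hazard is carried forward.
#' @export
fit_survival_spline <- function(curve,
                                smoothing = list(method = "monotone-interp",
                                                 tol = 0.005)) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(curve$time) < 4)
    stop("need at least 4 digitized points to fit", call. = FALSE)
  if (any(curve$survival <= 0))
    stop("survival must be positive to fit on the log scale; truncate the curve",
         call. = FALSE)
  method <- smoothing$method %||% "monotone-interp"
  tol <- smoothing$tol %||% 0.005
  t_max <- max(curve$time)
  logS <- log(curve$survival)

  if (method == "monotone-interp") {
    f_log <- stats::splinefun(curve$time, logS, method = "hyman")
    base_eval <- function(t) exp(pmin(0, f_log(t)))
  } else if (method == "smooth") {
    df <- smoothing$df %||% max(4, length(curve$time) - 2)
    ss <- stats::smooth.spline(curve$time, logS, df = df)
    grid <- seq(0, t_max, by = 1)
    pred <- pmin(0, stats::predict(ss, grid)$y)
    pred[1] <- 0                       # anchor S(0) = 1
    iso <- -stats::isoreg(grid, -pred)$yf
    iso <- cummin(iso)
    f_lin <- stats::approxfun(grid, iso, rule = 2)
    base_eval <- function(t) exp(pmin(0, f_lin(t)))
  } else {
    stop("unknown smoothing method '", method, "'", call. = FALSE)
  }

  # carry the last monthly hazard forward beyond the digitized range
  S_end <- base_eval(t_max)
  S_prev <- base_eval(max(t_max - 1, 0))
  h_tail <- if (S_prev > 0 && S_end > 0) max(0, log(S_prev) - log(S_end)) else 0
  eval_fn <- function(t) {
    t <- as.numeric(t)
    out <- base_eval(pmin(t, t_max))
    beyond <- t > t_max
    if (any(beyond))
      out[beyond] <- S_end * exp(-h_tail * (t[beyond] - t_max))
    pmin(1, pmax(0, out))
  }

  dev <- abs(eval_fn(curve$time) - curve$survival)
  if (max(dev) > tol)
    stop(sprintf("fitted spline misses input points by up to %.4f (> tol %.4f)",
                 max(dev), tol), call. = FALSE)

  structure(list(eval = eval_fn, knots = curve$time,
                 extrapolation_boundary = t_max,
                 tail_monthly_hazard = h_tail,
                 method = method, label = curve$label),
            class = "survival_fn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monthly event probability from a survival function
#'
#' Conditional probability of the event during `[m, m + 1)` given survival
#' to `m`: `(S(m) - S(m+1)) / S(m)`.
#'
#' @param S A `survival_fn` (or any function of time in months).
#' @param m Month (vectorised).
#' @return Probability in `[0, 1]`.
#' @export
monthly_event_probability <- function(S, m) {
  f <- if (inherits(S, "survival_fn")) S$eval else S
  s0 <- f(m)
  s1 <- f(m + 1)
  if (any(s0 <= 0))
    stop("survival is 0 at month ", paste(m[s0 <= 0], collapse = ", "),
         ": hazard undefined", call. = FALSE)
  pmin(1, pmax(0, (s0 - s1) / s0))
}

#' Monthly probability table with tail extrapolation and cure
#'
#' Builds the per-month event-probability table the transition engine
#' consumes: months up to `trial_end` use the fitted spline; months from
#' `trial_end + 1` to `cure_month` use the tail rule (default: carry the
#' last fitted monthly hazard forward; `"exponential"` refits a constant
#' hazard to the final 24 fitted months); months beyond `cure_month` are
#' exactly zero (patients disease-free that long are considered cured).
#'
#' @param S A `survival_fn`.
#' @param trial_end Last month supported by the digitized data
#'   (`<= cure_month`).
#' @param cure_month Cure month (default 96).
#' @param horizon Table length in months (default 300).
#' @param tail `"carry-forward-hazard"` or `"exponential"`.
#' @return Numeric vector of length `horizon`; entry `m` is the event
#'   probability during model month `m`.
#' @export
extrapolate_and_cure <- function(S, trial_end, cure_month = 96, horizon = 300,
                                 tail = c("carry-forward-hazard", "exponential")) {
  tail <- match.arg(tail)
  stopifnot(inherits(S, "survival_fn"), trial_end <= cure_month, trial_end >= 2)
  p <- numeric(horizon)
  fitted_months <- seq_len(min(trial_end, horizon))
  p[fitted_months] <- monthly_event_probability(S, fitted_months - 1)

  if (trial_end < cure_month) {
    gap <- (trial_end + 1L):min(cure_month, horizon)
    if (tail == "carry-forward-hazard") {
      p[gap] <- p[trial_end]
    } else {
      win <- max(1L, trial_end - 24L):trial_end
      # constant-hazard fit over the window: mean monthly log-survival drop
      h <- mean(-log1p(-p[win]))
      p[gap] <- 1 - exp(-h)
    }
  }
  if (cure_month < horizon) p[(cure_month + 1L):horizon] <- 0
  p
}

#' Landmark validation of model disease-free survival
#'
#' Compares the model's disease-free survival at a landmark month against a
#' trial-reported rate and returns the absolute deviation in percentage
#' points. Under the default `"recurrence_free"` convention, disease-free
#' occupancy is renormalized by the background (non-cancer) survival
#' implied by the life table, so the comparison isolates the recurrence
#' process the curve was calibrated to; `"df_including_death"` compares raw
#' disease-free occupancy (any death counts as an event, the usual trial
#' DFS convention).
#'
#' @param trace A `cohort_trace`.
#' @param landmark Length-2 numeric `c(month, survival_fraction)`.
#' @param params The `cea_parameters` used to run the trace (needed to
#'   reconstruct background survival).
#' @param convention `"recurrence_free"` (default) or `"df_including_death"`.
#' @return Absolute deviation in percentage points.
#' @export
validate_against_trial <- function(trace, landmark, params,
                                   convention = c("recurrence_free",
                                                  "df_including_death")) {
  convention <- match.arg(convention)
  month <- as.integer(landmark[1])
  target <- landmark[2]
  stopifnot(month >= 0, month <= trace$horizon, target >= 0, target <= 1)
  df_occ <- trace$occupancy[month + 1L, trace$space$idx_df]
  model <- if (convention == "recurrence_free" && month >= 1) {
    s_bg <- prod(1 - background_monthly_prob(params, seq_len(month)))
    df_occ / s_bg
  } else {
    df_occ
  }
  abs(model - target) * 100
}

#' Model disease-free survival curve from a trace
#'
#' Convenience accessor used for calibration reports: disease-free
#' occupancy at each cycle, optionally renormalized by background survival
#' (see [validate_against_trial()]).
#'
#' @inheritParams validate_against_trial
#' @param months Months at which to evaluate (default all cycles).
#' @return Data frame with columns `month` and `dfs`.
#' @export
model_dfs <- function(trace, params, months = 0:trace$horizon,
                      convention = c("recurrence_free", "df_including_death")) {
  convention <- match.arg(convention)
  df_occ <- trace$occupancy[months + 1L, trace$space$idx_df]
  if (convention == "recurrence_free") {
    q <- background_monthly_prob(params, seq_len(trace$horizon))
    s_bg <- c(1, cumprod(1 - q))[months + 1L]
    df_occ <- df_occ / s_bg
  }
  data.frame(month = months, dfs = df_occ)
}
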