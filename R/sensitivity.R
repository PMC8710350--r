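# Sensitivity analyses: one-way deterministic (tornado), probabilistic
# (PSA) with cost-effectiveness acceptability curves over a WTP sweep.

#' Define a one-way sensitivity range
#'
#' @param path Dotted parameter path into the parameter set (see
#'   [param_get()]), or one of the special paths `"wtp"` (threshold) and
#'   `"recurrence_hazard_factor.<STRATEGY>"` (multiplicative factor on the
#'   strategy's recurrence hazard, base 1).
#' @param low,high Range endpoints (`low <= high`).
#' @param label Optional display label.
#' @return Object of class `dsa_range`.
#' @export
dsa_range <- function(path, low, high, label = path) {
  if (low > high) stop("dsa_range: low > high for ", path, call. = FALSE)
  structure(list(path = path, low = low, high = high, label = label),
            class = "dsa_range")
}

# apply one DSA value; returns list(params, wtp)
apply_dsa_value <- function(params, wtp, path, value) {
  if (path == "wtp") return(list(params = params, wtp = value))
  if (startsWith(path, "recurrence_hazard_factor.")) {
    s <- sub("^recurrence_hazard_factor\\.", "", path)
    if (is.null(params$recurrence_prob[[s]]))
      stop("unknown strategy in DSA path: ", s, call. = FALSE)
    if (value < 0) stop("hazard factor must be >= 0", call. = FALSE)
    params$recurrence_prob[[s]] <- 1 - (1 - params$recurrence_prob[[s]])^value
    return(list(params = params, wtp = wtp))
  }
  params <- param_set(params, path, value)
  validate_parameters(params)
  list(params = params, wtp = wtp)
}

# base value a DSA range pivots around
dsa_base_value <- function(params, wtp, path) {
  if (path == "wtp") return(wtp)
  if (startsWith(path, "recurrence_hazard_factor.")) return(1)
  v <- param_get(params, path)
  if (!is.numeric(v) || length(v) != 1)
    stop("DSA path must address a scalar: ", path, call. = FALSE)
  v
}

#' Default one-way sensitivity ranges
#'
#' A standard set: +/-20% recurrence hazard for the oxaliplatin doublets,
#' the FOLFOX administration cost from 0 to base (monthly component),
#' hepatectomy cost and metastatic line-1 cost +/-50%, recurrence
#' disability weight +/-25%, discount rate 0-10%, and the WTP threshold
#' from half to three times its base value.
#'
#' @param params A `cea_parameters`.
#' @param wtp Base WTP threshold.
#' @return List of [dsa_range()] objects.
#' @export
default_dsa_ranges <- function(params, wtp = params$wtp) {
  admin <- params$costs$adjuvant$FOLFOX_6MO[["administration"]]
  w_rec <- params$disability_weights$recurrence
  list(
    dsa_range("recurrence_hazard_factor.CAPOX_3MO", 0.8, 1.2,
              "Recurrence hazard after CAPOX 3MO (x0.8-x1.2)"),
    dsa_range("recurrence_hazard_factor.FOLFOX_6MO", 0.8, 1.2,
              "Recurrence hazard after FOLFOX 6MO (x0.8-x1.2)"),
    dsa_range("costs.adjuvant.FOLFOX_6MO.administration", 0, admin,
              "FOLFOX 6MO administration cost (I$0-base)"),
    dsa_range("costs.hepatectomy", params$costs$hepatectomy * 0.5,
              params$costs$hepatectomy * 1.5, "Hepatectomy cost (+/-50%)"),
    dsa_range("costs.metastatic.line1_monthly",
              params$costs$metastatic$line1_monthly * 0.5,
              params$costs$metastatic$line1_monthly * 1.5,
              "Metastatic line 1 monthly cost (+/-50%)"),
    dsa_range("disability_weights.recurrence",
              max(0, w_rec * 0.75), min(1, w_rec * 1.25),
              "Recurrence disability weight (+/-25%)"),
    dsa_range("discount_rate_annual", 0, 0.10, "Annual discount rate (0-10%)"),
    dsa_range("wtp", wtp / 2, wtp * 3, "WTP threshold (x0.5-x3)")
  )
}

# frontier ICER of the strategy immediately above the optimal one
dsa_outcome <- function(res, wtp) {
  opt <- select_optimal(res, wtp)
  frontier <- res[res$dominance == "on_frontier", ]
  frontier <- frontier[order(frontier$dalys_averted), ]
  i <- match(opt, frontier$strategy)
  if (is.na(i) || i == nrow(frontier)) return(NA_real_)
  frontier$icer[i + 1L]
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full base-case analysis with each parameter at its low and
#' high value (all others at base) and records, at each endpoint, the ICER
#' of the next frontier strategy above the optimal one and whether the
#' optimal strategy changes. Rows are sorted by output swing, descending,
#' ready for a tornado plot.
#'
#' @param ranges List of [dsa_range()] objects.
#' @param params A `cea_parameters`.
#' @param strategies Named strategy list (default [default_strategies()]).
#' @param wtp WTP threshold (default `params$wtp`).
#' @return Data frame with columns `parameter`, `low`, `high`, `base`,
#'   `icer_low`, `icer_high`, `icer_base`, `optimal_low`, `optimal_high`,
#'   `optimal_changed`, `swing`.
#' @export
one_way_dsa <- function(ranges, params, strategies = default_strategies(),
                        wtp = params$wtp) {
  base_res <- run_cea(params, strategies, wtp)
  base_opt <- select_optimal(base_res, wtp)
  base_icer <- dsa_outcome(base_res, wtp)

  eval_at <- function(path, value) {
    mod <- apply_dsa_value(params, wtp, path, value)
    res <- run_cea(mod$params, strategies, mod$wtp)
    list(icer = dsa_outcome(res, mod$wtp),
         optimal = select_optimal(res, mod$wtp))
  }

  rows <- lapply(ranges, function(r) {
    lo <- eval_at(r$path, r$low)
    hi <- eval_at(r$path, r$high)
    data.frame(parameter = r$label, path = r$path,
               low = r$low, high = r$high,
               base = dsa_base_value(params, wtp, r$path),
               icer_low = lo$icer, icer_high = hi$icer, icer_base = base_icer,
               optimal_low = lo$optimal, optimal_high = hi$optimal,
               optimal_changed = !identical(lo$optimal, base_opt) ||
                 !identical(hi$optimal, base_opt))
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$icer_high - out$icer_low)
  out$swing[is.na(out$icer_high) & is.na(out$icer_low)] <- 0
  out <- out[order(-ifelse(is.na(out$swing), -Inf, out$swing)), ]
  rownames(out) <- NULL
  attr(out, "base_optimal") <- base_opt
  attr(out, "base_icer") <- base_icer
  out
}

# beta draw parameterized by mean and coefficient of variation
beta_draw <- function(n, mean, cv, max_attempts = 100L) {
  if (cv <= 0 || any(mean <= 0) || any(mean >= 1))
    return(rep(mean, length.out = n))
  v <- pmin((cv * mean)^2, 0.95 * mean * (1 - mean))
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  for (i in seq_len(max_attempts)) {
    x <- stats::rbeta(n, a, b)
    if (all(x >= 0 & x <= 1)) return(x)
  }
  stop("beta draw failed to produce in-range values", call. = FALSE)
}

# gamma draw parameterized by mean and coefficient of variation
gamma_draw <- function(n, mean, cv) {
  if (cv <= 0 || any(mean <= 0)) return(rep(mean, length.out = n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Samples a perturbed copy of the base parameters: per-strategy recurrence
#' curves get a log-normal multiplicative hazard factor (mean 1);
#' post-recurrence mortality rows are scaled by beta draws around the
#' stratum base probability; disability weights and TRAE probabilities are
#' beta-distributed around their means; cost entries (adjuvant components,
#' surveillance, metastatic lines, hepatectomy, TRAE unit costs) are
#' gamma-distributed. The coefficient of variation `cv` controls every
#' distribution; `cv = 0` reproduces the base set exactly. Per-component
#' coefficients (entries `hazard`, `crc_death`, `weights`, `costs`, `trae`
#' of `components`, defaulting to `base$psa$components`) override `cv` for
#' that block, so individual input classes can be held fixed or varied on
#' their own. Draws are independent across parameters; the caller controls
#' the RNG stream.
#'
#' @param base A `cea_parameters` object.
#' @param cv Default coefficient of variation (default `base$psa$cv`).
#' @param components Optional named numeric vector/list of per-block
#'   coefficients of variation.
#' @return A valid `cea_parameters` object.
#' @export
draw_parameter_set <- function(base, cv = base$psa$cv %||% 0.2,
                               components = base$psa$components %||% NULL) {
  ccv <- function(nm) {
    v <- components[[nm]] %||% cv
    if (is.na(v)) cv else v
  }
  if (cv <= 0 && (is.null(components) || all(unlist(components) <= 0)))
    return(base)
  p <- base

  cv_h <- ccv("hazard")
  if (cv_h > 0) {
    sdlog <- sqrt(log(1 + cv_h^2))
    for (s in names(p$recurrence_prob)) {
      f <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      p$recurrence_prob[[s]] <- 1 - (1 - p$recurrence_prob[[s]])^f
    }
  }
  cv_c <- ccv("crc_death")
  if (cv_c > 0) {
    for (s in RECURRENCE_STRATA) {
      b0 <- p$crc_death_prob[s, 1L]
      draw <- beta_draw(1, b0, cv_c)
      p$crc_death_prob[s, ] <- pmin(1, p$crc_death_prob[s, ] * (draw / b0))
    }
  }
  cv_w <- ccv("weights")
  if (cv_w > 0) {
    dw <- p$disability_weights
    dw$disease_free <- beta_draw(1, dw$disease_free, cv_w)
    dw$recurrence <- beta_draw(1, dw$recurrence, cv_w)
    dw$hepatectomy <- beta_draw(1, dw$hepatectomy, cv_w)
    p$disability_weights <- dw
  }
  cv_k <- ccv("costs")
  if (cv_k > 0) {
    co <- p$costs
    for (s in names(co$adjuvant)) {
      x <- co$adjuvant[[s]]
      pos <- x > 0
      x[pos] <- gamma_draw(sum(pos), 1, cv_k) * x[pos]
      co$adjuvant[[s]] <- x
    }
    co$surveillance_monthly <- gamma_draw(1, co$surveillance_monthly, cv_k)
    for (nm in c("line1_monthly", "line2_monthly", "bsc_monthly"))
      co$metastatic[[nm]] <- gamma_draw(1, co$metastatic[[nm]], cv_k)
    co$hepatectomy <- gamma_draw(1, co$hepatectomy, cv_k)
    p$costs <- co
  }
  cv_t <- ccv("trae")
  if (cv_t > 0) {
    for (s in names(p$trae$adjuvant)) {
      tab <- p$trae$adjuvant[[s]]
      tab$probability <- vapply(tab$probability, function(m) beta_draw(1, m, cv_t),
                                numeric(1))
      tab$cost <- gamma_draw(nrow(tab), 1, cv_t) * tab$cost
      p$trae$adjuvant[[s]] <- tab
    }
    for (l in names(p$trae$metastatic)) {
      tab <- p$trae$metastatic[[l]]
      tab$probability <- vapply(tab$probability, function(m) beta_draw(1, m, cv_t),
                                numeric(1))
      tab$cost <- gamma_draw(nrow(tab), 1, cv_t) * tab$cost
      p$trae$metastatic[[l]] <- tab
    }
  }
  validate_parameters(p)
  p
}

# cost and effect (DALYs averted vs NO_CHEMO) for each strategy
psa_evaluate <- function(params, strategies) {
  per <- lapply(strategies, function(s) {
    tr <- run_cohort(s, params)
    c(cost = accrue_costs(tr, s, params),
      dalys = compute_dalys(tr, params$disability_weights, s, params))
  })
  cost <- vapply(per, `[`, numeric(1), 1)
  dalys <- vapply(per, `[`, numeric(1), 2)
  list(cost = cost, effect = dalys["NO_CHEMO"] - dalys)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: for each iteration a
#' parameter set is drawn with [draw_parameter_set()], every strategy is
#' run through the cohort engine and economics, and the optimal strategy at
#' the evaluation threshold is the net-monetary-benefit argmax. Reproducible
#' for a given seed.
#'
#' @param params Base `cea_parameters`.
#' @param strategies Named strategy list including `NO_CHEMO`.
#' @param n Number of iterations.
#' @param seed RNG seed.
#' @param wtp Evaluation WTP threshold (default `params$wtp`).
#' @param cv Coefficient of variation for the draws (default
#'   `params$psa$cv`).
#' @return Object of class `cea_psa`: list with `cost` and `effect`
#'   (`n x strategies` matrices), `probability_optimal` (named fractions
#'   summing to 1), `wtp`, `n`, `seed`.
#' @export
run_psa <- function(params, strategies = default_strategies(), n, seed = 1L,
                    wtp = params$wtp, cv = params$psa$cv %||% 0.2) {
  stopifnot(n >= 1, "NO_CHEMO" %in% names(strategies))
  K <- length(strategies)
  cost <- matrix(NA_real_, n, K, dimnames = list(NULL, names(strategies)))
  effect <- cost
  with_seed(seed, {
    for (i in seq_len(n)) {
      pi <- draw_parameter_set(params, cv)
      ev <- psa_evaluate(pi, strategies)
      cost[i, ] <- ev$cost
      effect[i, ] <- ev$effect
    }
  })
  b <- wtp * effect - cost
  opt <- names(strategies)[max.col(b, ties.method = "first")]
  prob <- table(factor(opt, levels = names(strategies))) / n
  structure(
    list(cost = cost, effect = effect,
         probability_optimal = c(prob),
         optimal = opt, wtp = wtp, n = n, seed = seed, cv = cv),
    class = "cea_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Re-evaluates the net-monetary-benefit argmax of every stored PSA
#' iteration at each threshold on a WTP grid (no re-simulation) and returns
#' the probability each strategy is optimal. Default grid: 25 evenly spaced
#' points from half to three times the base threshold used in the model
#' (I$6,503.29 to I$39,019.72).
#'
#' @param psa A `cea_psa` object.
#' @param wtp_grid Numeric vector of thresholds.
#' @return Data frame (long) with columns `wtp`, `strategy`, `probability`;
#'   probabilities at each threshold sum to 1.
#' @export
ceac <- function(psa, wtp_grid = seq(6503.29, 39019.72, length.out = 25)) {
  stopifnot(inherits(psa, "cea_psa"), length(wtp_grid) >= 1)
  strategies <- colnames(psa$cost)
  rows <- lapply(wtp_grid, function(w) {
    b <- w * psa$effect - psa$cost
    opt <- strategies[max.col(b, ties.method = "first")]
    prob <- table(factor(opt, levels = strategies)) / psa$n
    data.frame(wtp = w, strategy = strategies,
               probability = as.numeric(prob))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
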