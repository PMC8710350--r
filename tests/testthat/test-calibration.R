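# Spline calibration: KM points -> survival function -> monthly
# probabilities, tail extrapolation, cure, landmark validation.

test_that("km_curve validates digitized input", {
  expect_s3_class(km_curve(c(0, 12, 24), c(1, 0.9, 0.8)), "km_curve")
  expect_error(km_curve(c(0, 12, 24), c(1, 0.8, 0.9)), "increases")
  expect_error(km_curve(c(0, 12, 12), c(1, 0.9, 0.8)), "strictly increasing")
  expect_error(km_curve(c(1, 12, 24), c(1, 0.9, 0.8)), "start")
  expect_error(km_curve(c(0, 12), c(1, 1.2)), "increases|\\[0,1\\]")
})

test_that("near-linear points interpolate sensibly", {
  cur <- km_curve(c(0, 12, 24, 36), c(1, 0.9, 0.8, 0.7))
  S <- fit_survival_spline(cur)
  expect_gte(S$eval(18), 0.84)
  expect_lte(S$eval(18), 0.86)
  # passes through the digitized points
  expect_equal(S$eval(cur$time), cur$survival, tolerance = 1e-9)
})

test_that("exponential points are recovered between knots", {
  lam <- 0.01
  tt <- seq(0, 60, by = 6)
  cur <- km_curve(tt, exp(-lam * tt))
  S <- fit_survival_spline(cur)
  expect_equal(S$eval(30), exp(-0.3), tolerance = 0.005 / exp(-0.3))
  expect_lt(abs(S$eval(45) - exp(-0.45)), 0.005)
})

test_that("smoothing fit handles noisy digitizations monotonically", {
  lam <- 0.012
  cur <- generate_km_points(list(family = "exponential", lambda = lam),
                            times = seq(0, 60, by = 3), n_at_risk = 800,
                            seed = 42)
  S <- fit_survival_spline(cur, smoothing = list(method = "smooth", tol = 0.05))
  grid <- 0:60
  vals <- S$eval(grid)
  expect_true(all(diff(vals) <= 1e-9))
  expect_equal(S$eval(0), 1)
  expect_lt(abs(S$eval(40) - exp(-lam * 40)), 0.05)
})

test_that("too-few or non-positive survival points are rejected", {
  expect_error(fit_survival_spline(km_curve(c(0, 12, 24), c(1, 0.9, 0.8))),
               "at least 4")
  expect_error(
    fit_survival_spline(km_curve(c(0, 12, 24, 36), c(1, 0.5, 0.2, 0))),
    "positive")
})

test_that("monthly event probability follows the hazard identity", {
  lam <- 0.02
  S <- fit_survival_spline(km_curve(0:80, exp(-lam * (0:80))))
  p <- monthly_event_probability(S, c(0, 10, 40))
  expect_equal(p, rep(1 - exp(-lam), 3), tolerance = 1e-6)
  # pure arithmetic: S(m)=0.5, S(m+1)=0.25 -> 0.5
  f <- function(t) ifelse(t <= 10, 0.5, 0.25)
  expect_equal(monthly_event_probability(f, 10), 0.5)
  # constant survival -> 0
  expect_equal(monthly_event_probability(function(t) rep(0.7, length(t)), 3), 0)
  # zero survival -> undefined hazard
  expect_error(monthly_event_probability(function(t) rep(0, length(t)), 3),
               "hazard undefined")
})

test_that("extrapolation carries the last hazard and cure zeroes the tail", {
  lam <- 0.004
  S <- fit_survival_spline(km_curve(0:60, exp(-lam * (0:60))))
  p <- extrapolate_and_cure(S, trial_end = 60, cure_month = 96, horizon = 300)
  expect_length(p, 300)
  expect_equal(p[61:96], rep(p[60], 36), tolerance = 1e-9)
  expect_equal(p[97:300], rep(0, 204))
  # exponential tail rule gives the same answer for truly constant hazard
  p2 <- extrapolate_and_cure(S, 60, 96, 300, tail = "exponential")
  expect_equal(p2[70], p[70], tolerance = 1e-6)
  # cumulative incidence by cure month close to the analytic value
  ci_model <- 1 - prod(1 - p[1:96])
  ci_true <- 1 - exp(-lam * 96)
  expect_lt(abs(ci_model - ci_true) / ci_true, 0.10)
})

test_that("constant hazards round-trip through the calibration pipeline", {
  for (lam in c(0.002, 0.01, 0.03)) {
    cur <- generate_km_points(list(family = "exponential", lambda = lam),
                              times = seq(0, 60, by = 6))
    p <- calibrate_recurrence(cur, trial_end = 60, cure_month = 96,
                              horizon = 300)
    p_true <- 1 - exp(-lam)
    expect_lt(max(abs(p[1:96] - p_true) / p_true), 0.05)
  }
})

test_that("landmark validation measures percentage-point deviation", {
  params <- toy_params(start_age = 60, p_rec = 0.01, p_crc = 0.03,
                       q_annual = annual_from_monthly(0.002), cure_month = 96)
  tr <- run_cohort(toy_strategies()$CAPOX_3MO, params)
  # identity: landmark equal to the model's own DFS -> 0
  own <- model_dfs(tr, params, months = 60)$dfs
  expect_equal(validate_against_trial(tr, c(60, own), params), 0)
  # arithmetic: landmark 0.60, model 0.63 -> 3.0
  expect_equal(validate_against_trial(tr, c(60, own - 0.03), params), 3,
               tolerance = 1e-9)
  # the renormalized convention recovers the generating recurrence curve
  expect_equal(own, 0.99^60, tolerance = 1e-9)
  # raw disease-free convention counts background deaths as events
  raw <- validate_against_trial(tr, c(60, 0.99^60), params,
                                convention = "df_including_death")
  expect_gt(raw, 0)
})

test_that("model calibrated from a landmark-generating curve hits the landmark", {
  # the full loop: hazard -> KM points -> spline -> monthly table -> cohort
  # engine -> DFS at 60 months within 1.5 percentage points of the truth
  lam <- 0.009
  cur <- generate_km_points(list(family = "weibull", lambda = lam, shape = 0.9),
                            times = seq(0, 72, by = 6))
  p_cal <- calibrate_recurrence(cur, trial_end = 72, cure_month = 96,
                                horizon = 300)
  params <- default_params()
  params$recurrence_prob$CAPOX_3MO <- p_cal
  tr <- run_cohort(default_strategies()$CAPOX_3MO, params)
  truth <- exp(-(lam * 60)^0.9)
  dev <- validate_against_trial(tr, c(60, truth), params)
  expect_lt(dev, 1.5)
})
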