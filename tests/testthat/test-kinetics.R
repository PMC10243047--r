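test_that("log-linear growth fitting recovers noiseless parameters to machine precision", {
  set.seed(11)
  for (mu in c(-0.1, -0.01, 0, 0.028, 0.1)) {
    times <- sort(c(0, sample(1:200, 4)))
    fit <- fit_growth(exp_series(times = times, mu = mu, c0 = 1e5))
    expect_equal(fit$mu, mu, tolerance = 1e-10)
    expect_equal(fit$initial_density, 1e5, tolerance = 1e-8)
  }
  const <- fit_growth(culture_time_series(c(0, 24, 48), rep(2e5, 3)))
  expect_equal(const$mu, 0)
  expect_error(fit_growth(culture_time_series(0, 1e5)), "two")
  expect_error(fit_growth(c(1e5, -1), times = c(0, 24)), "positive")
})

test_that("density prediction inverts the fitted exponential", {
  fit <- list(mu = 0.028, initial_density = 1e5)
  expect_equal(predict_density(fit, 0), 1e5)
  expect_equal(predict_density(list(mu = 0, initial_density = 1e5),
                               c(0, 100, 500)), rep(1e5, 3))
  expect_equal(predict_density(fit, log(27.4) / 0.028), 2.74e6)
  expect_error(predict_density(fit, -1), "non-negative")
})

test_that("fold expansion is the ratio of final to initial density", {
  expect_equal(fold_expansion(1e5, 2.74e6), 27.4)
  expect_equal(fold_expansion(1e5, 2.45e6), 24.5)
  expect_equal(fold_expansion(3e5, 3e5), 1)
  expect_error(fold_expansion(0, 1e6), "positive")
})

test_that("R^2 matches its defining sum-of-squares form", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 4, 6)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "equal-length")
})

test_that("exchange correction resets baselines and conserves cumulative mass", {
  # no events: cumulative change is just the concentration difference
  s <- culture_time_series(c(0, 24, 48), c(1e5, 2e5, 4e5),
                           glucose = c(2.0, 1.8, 1.5))
  corr <- apply_exchange_correction(s, "glucose")
  expect_equal(corr$cumulative_change, c(0, -0.2, -0.5))

  # single 50% event at a sample time: baseline resets to
  # (1 - f) C(tau-) + f C_f = 0.5 * 1.0 + 0.5 * 2.0 = 1.5
  ev <- data.frame(time_h = 24, fraction = 0.5, fresh_glucose = 2.0)
  s <- culture_time_series(c(0, 24, 48), c(1e5, 2e5, 4e5),
                           glucose = c(1.2, 1.0, 1.1), exchange_events = ev)
  corr <- apply_exchange_correction(s, "glucose")
  expect_equal(corr$cumulative_change,
               c(0, 1.0 - 1.2, (1.0 - 1.2) + (1.1 - 1.5)))

  # conservation: total change equals the mass-ledger oracle regardless of
  # how many events split the window, including events between samples
  fit <- list(mu = 0.028, initial_density = 1e5)
  ev <- data.frame(time_h = c(24, 60, 120), fraction = c(0.5, 0.3, 0.5),
                   fresh_glucose = c(2.0, 1.8, 2.0))
  times <- seq(0, 168, by = 12)
  conc <- predict_metabolite_profile(fit, 2e-12, 2.0, times,
                                     direction = "consumption",
                                     exchange_events = ev,
                                     metabolite = "glucose")
  s <- culture_time_series(times, predict_density(fit, times),
                           glucose = conc, exchange_events = ev)
  corr <- apply_exchange_correction(s, "glucose")
  # oracle: C(T) - C(0) minus the exchange jumps f (C_f - C(tau-)),
  # with C(tau-) taken from the generating closed form
  pre <- predict_metabolite_profile(fit, 2e-12, 2.0, ev$time_h,
                                    direction = "consumption",
                                    exchange_events = ev,
                                    metabolite = "glucose")
  jumps <- sum(ev$fraction * (ev$fresh_glucose - pre))
  expect_equal(corr$cumulative_change[length(times)],
               conc[length(times)] - conc[1] - jumps, tolerance = 1e-6)
  expect_error(
    culture_time_series(c(0, 24), c(1e5, 2e5), glucose = c(2, 1.9),
                        exchange_events = data.frame(time_h = 30,
                                                     fraction = 0.5,
                                                     fresh_glucose = 2)),
    "within")
})

test_that("specific metabolite rates carry dimensionally consistent units", {
  # constant density 1e6 cells/ml, 0.5 g/l consumed over 48 h:
  # q = 0.5 / (48 * 1e6 cells/ml * 1000 ml/l) g per cell per hour
  s <- culture_time_series(c(0, 48), c(1e6, 1e6), glucose = c(2.0, 1.5))
  r <- specific_metabolite_rate(s, "glucose",
                                fit = list(mu = 0, initial_density = 1e6))
  expect_equal(r$direction, "consumption")
  expect_equal(r$q, 0.5 / (48 * 1e6 * 1000))
  expect_equal(r$interval_rates$q_signed, -0.5 / (48 * 1e6 * 1000))
  # zero change -> zero rate
  s0 <- culture_time_series(c(0, 48), c(1e6, 1e6), glucose = c(2, 2),
                            lactate = c(1, 1))
  expect_equal(specific_metabolite_rate(
    s0, "glucose", fit = list(mu = 0, initial_density = 1e6))$q_signed, 0)
  expect_error(specific_metabolite_rate(s0, "alanine"), "not present")
})

test_that("profile prediction and rate estimation are mutually inverse", {
  fit <- list(mu = 0.028, initial_density = 1e5)
  ev <- data.frame(time_h = c(24, 72, 120), fraction = 0.5,
                   fresh_glucose = 2.0)
  times <- seq(0, 168, by = 24)
  for (q_true in c(1e-12, 3e-12)) {
    conc <- predict_metabolite_profile(fit, q_true, 2.0, times,
                                       direction = "consumption",
                                       exchange_events = ev,
                                       metabolite = "glucose")
    s <- culture_time_series(times, predict_density(fit, times),
                             glucose = conc, exchange_events = ev)
    r <- specific_metabolite_rate(s, "glucose", fit = fit)
    expect_equal(r$q_signed, -q_true, tolerance = 1e-6)
    expect_equal(r$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("metabolite profile handles t = 0, the mu -> 0 limit and depletion", {
  fit <- list(mu = 0.028, initial_density = 1e5)
  expect_equal(predict_metabolite_profile(fit, 3e-12, 2.0, 0), 2.0)
  tiny <- list(mu = 1e-12, initial_density = 1e6)
  zero <- list(mu = 0, initial_density = 1e6)
  tt <- c(0, 48, 96)
  expect_equal(predict_metabolite_profile(tiny, 1e-12, 2, tt),
               predict_metabolite_profile(zero, 1e-12, 2, tt),
               tolerance = 1e-9)
  expect_equal(predict_metabolite_profile(zero, 1e-12, 2, tt),
               2 - 1e-12 * 1000 * 1e6 * tt)
  expect_warning(
    out <- predict_metabolite_profile(fit, 1e-10, 0.5, c(0, 168),
                                      direction = "consumption"),
    "floored")
  expect_equal(out[2], 0)
})

test_that("lactate:glucose yield follows corrected changes and ignores neutral exchanges", {
  s <- culture_time_series(c(0, 48), c(1e5, 4e5),
                           glucose = c(2.0, 1.0), lactate = c(0, 0.9))
  expect_equal(lactate_glucose_ratio(s), 0.9)
  s0 <- culture_time_series(c(0, 48), c(1e5, 4e5),
                            glucose = c(2.0, 1.0), lactate = c(0.5, 0.5))
  expect_equal(lactate_glucose_ratio(s0), 0)
  flat <- culture_time_series(c(0, 48), c(1e5, 4e5),
                              glucose = c(2, 2), lactate = c(0, 1))
  expect_error(lactate_glucose_ratio(flat), "undefined")
  # an exchange replacing medium with fresh medium at the current
  # concentrations changes nothing: ratio invariant
  fit <- list(mu = 0.028, initial_density = 1e5)
  times <- seq(0, 168, by = 24)
  glc <- predict_metabolite_profile(fit, 3e-12, 2.0, times,
                                    direction = "consumption")
  lac <- predict_metabolite_profile(fit, 2.7e-12, 0, times,
                                    direction = "production")
  base <- culture_time_series(times, predict_density(fit, times),
                              glucose = glc, lactate = lac)
  ev <- data.frame(time_h = 72, fraction = 0.5,
                   fresh_glucose = glc[times == 72],
                   fresh_lactate = lac[times == 72])
  with_ev <- culture_time_series(times, predict_density(fit, times),
                                 glucose = glc, lactate = lac,
                                 exchange_events = ev)
  expect_equal(lactate_glucose_ratio(with_ev), lactate_glucose_ratio(base),
               tolerance = 1e-9)
  expect_equal(lactate_glucose_ratio(base), 0.9, tolerance = 1e-9)
})
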