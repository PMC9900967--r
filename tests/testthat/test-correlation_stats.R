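test_that("connected estimator: unit lag-0 value and the classic -1/N bias", {
  set.seed(21)
  n <- 200
  reps <- replicate(3000, {
    ce <- connected_acf_timeavg(rnorm(n), dt = 1, max_lag = 30,
                                lags = c(0, 5, 10, 20))
    ce$values[-1]
  })
  ce0 <- connected_acf_timeavg(rnorm(n), dt = 1, max_lag = 50)
  expect_equal(ce0$values[1], 1)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - (-1 / n)), 3 * se)
  expect_error(connected_acf_timeavg(rep(3, 100), dt = 1, max_lag = 10),
               "variance")
})

test_that("connected estimator tracks the OU closed form within sampling error", {
  nrep <- 40
  series <- lapply(1:nrep, function(i) ou_exact(20000, 0.05, theta = 1,
                                                D = 1, seed = 100 + i))
  lag_t <- c(0.5, 1, 2)
  ce <- connected_acf_timeavg(series, dt = 0.05, max_lag = 3, lags = lag_t)
  idx <- match(lag_t, ce$lags)
  # standard error across independent series
  per <- sapply(series, function(x)
    connected_acf_timeavg(x, 0.05, 3, lags = lag_t)$values[idx])
  se <- apply(per, 1, sd) / sqrt(nrep)
  expect_true(all(abs(ce$values[idx] - exp(-lag_t)) < 3 * se + 1e-3))
})

test_that("non-connected ensemble estimator matches the telegraph closed form", {
  # symmetric telegraph with flip rate w per state decorrelates as exp(-2 w tau)
  w <- 0.02
  trs <- lapply(1:30, function(i)
    2 * as.numeric(generate_telegraph(w, 4e4, dt = 1, seed = i)) - 1)
  ce <- nonconnected_acf_ensemble(trs, dt = 1, max_lag = 100,
                                  lags = c(1, 10, 25, 50), normalize = "none")
  expect_equal(ce$values, exp(-2 * w * ce$lags), tolerance = 0.05)
  ce_n <- nonconnected_acf_ensemble(trs, dt = 1, max_lag = 100,
                                    lags = c(1, 10, 25, 50))
  expect_equal(ce_n$values[1], 1)
  expect_true(all(ce_n$values <= 1 + 1e-9 & ce_n$values > 0))
  # unequal sampling intervals are rejected
  t1 <- trajectory(rnorm(100), dt = 1)
  t2 <- trajectory(rnorm(100), dt = 2)
  expect_error(nonconnected_acf_ensemble(list(t1, t2), max_lag = 10),
               "unequal")
})

test_that("mixture correlation: point mass, flat 1/omega case, and quadrature", {
  w1 <- 0.05
  rd <- rate_distribution(omega_min = w1, omega_max = w1)
  tg <- seq(0, 100, by = 5)
  expect_equal(mixture_correlation(rd, tg), exp(-w1 * tg), tolerance = 1e-12)
  # p ~ 1/omega: flat in log tau up to log corrections
  rdf <- rate_distribution(function(w) 1 / w, 1e-6, 1)
  tg2 <- exp(seq(log(10), log(1e3), length.out = 20))
  sl <- fit_loglog_slope(tg2, mixture_correlation(rdf, tg2))
  expect_lt(abs(sl$slope), 0.15)
})

test_that("asymptotic correlation obeys its limits and gamma = beta + 2", {
  pot <- double_well_potential(0)
  tg <- exp(seq(log(10), log(1e5), length.out = 30))
  cinf <- asymptotic_correlation(pot, Tx = 1e-3, Ts = Inf, omega0 = 1, tg)
  expect_lt(diff(range(cinf)), 1e-12)
  cs <- asymptotic_correlation(pot, Tx = 0.1, Ts = 0.04, omega0 = 1, tg)
  expect_equal(fit_loglog_slope(tg, cs)$slope, -0.1 / 0.08, tolerance = 1e-6)
  fs <- asymptotic_fptd(pot, Tx = 0.1, Ts = 0.04, omega0 = 1, tg)
  expect_equal(fit_loglog_slope(tg, cs)$slope - fit_loglog_slope(tg, fs)$slope,
               2, tolerance = 1e-9)
})

test_that("finite-size correction: white-noise bias, vanishing limit, MC oracle", {
  # discrete white noise: corrected value ~ -1/T at positive lags
  lg <- seq(0, 100, by = 1)
  wn <- correlation_estimate(lg, c(1, rep(0, 100)), "model")
  fc <- finite_size_correction(wn, T_obs = 100)
  expect_lt(abs(fc$values[10] - (-1 / 100)), 1e-4)
  # T_obs -> infinity: correction vanishes uniformly
  lg2 <- seq(0, 1e6, length.out = 2001)
  slow <- correlation_estimate(lg2, exp(-lg2 / 20), "model")
  fc2 <- finite_size_correction(slow, T_obs = 1e6)
  expect_lt(max(abs(fc2$values - slow$values)), 1e-3)
  expect_error(finite_size_correction(wn, T_obs = 1000), "cover")

  # ensemble Monte-Carlo oracle: OU with tau_c = T_obs / 10
  tau_c <- 20; T_obs <- 200; dt <- 0.1
  lg3 <- seq(0, T_obs, by = dt)
  model <- correlation_estimate(lg3, exp(-lg3 / tau_c), "model")
  pred <- finite_size_correction(model, T_obs)
  lags_chk <- c(5, 20, 50, 100)
  set.seed(33)
  nrep <- 1200
  vals <- t(replicate(nrep, {
    x <- ou_exact(length(lg3), dt, theta = 1 / tau_c, D = 1 / tau_c,
                  seed = sample.int(1e8, 1))
    ce <- connected_acf_timeavg(x, dt, max_lag = 100, lags = lags_chk,
                                normalize_variance = FALSE)
    ce$values[match(lags_chk, ce$lags)]
  }))
  emp <- colMeans(vals); se <- apply(vals, 2, sd) / sqrt(nrep)
  z <- abs(emp - pred$values[match(lags_chk, pred$lags)]) / se
  expect_true(all(z < 3))
  # the corrected model crosses zero: apparent anti-correlations
  expect_true(any(pred$values < 0))
  expect_true(any(emp < 0))
})

test_that("first-order mean-variance correction equals the stated integral", {
  lg <- seq(0, 50, by = 0.1)
  cv <- exp(-lg / 4)
  model <- correlation_estimate(lg, cv, "model")
  fc <- finite_size_correction(model, T_obs = 50, method = "mean_variance")
  V <- 2 / 50 * sum(diff(lg) * (head((1 - lg / 50) * cv, -1) +
                                  tail((1 - lg / 50) * cv, -1)) / 2)
  expect_equal(fc$values, cv - V, tolerance = 1e-4)
  expect_equal(fc$mean_variance, V, tolerance = 1e-4)
})

test_that("anti-correlations emerge in time-averaged but not ensemble estimates", {
  # frozen-rate ensemble with slowest rates ~ 1/T_obs
  Tx <- 0.15; Ts <- 0.15; T_obs <- 2e4
  set.seed(41)
  s <- rnorm(300, 1, sqrt(Ts)); s <- s[s^2 > 2 * Tx]
  w <- kramers_rate(s, double_well_potential(1), Tx)
  series <- lapply(seq_along(w), function(i)
    2 * as.numeric(generate_telegraph(w[i], T_obs, dt = 2, seed = 1000 + i)) - 1)
  lag_t <- c(4, 50, 500, 2000, 5000, 8000)
  varying <- vapply(series, sd, numeric(1)) > 0  # connected ACF needs variance
  conn <- connected_acf_timeavg(series[varying], dt = 2, max_lag = 8000,
                                lags = lag_t)
  nonc <- nonconnected_acf_ensemble(series, dt = 2, max_lag = 8000,
                                    lags = lag_t, normalize = "none")
  expect_lt(min(conn$values), -0.01)      # time-averaged goes negative
  expect_gt(min(nonc$values), 0)          # ensemble stays positive
})

test_that("finite-size correction magnitude grows with the slow noise level", {
  Tx <- 0.15; T_obs <- 2e4
  vs <- vapply(c(0.02, 0.1, 0.3), function(Ts) {
    set.seed(11)
    s <- rnorm(3e4, 1, sqrt(Ts)); s <- s[s^2 > 2 * Tx]
    w <- kramers_rate(s, double_well_potential(1), Tx)
    lg <- seq(0, T_obs, length.out = 2001)
    cm <- correlation_estimate(lg, vapply(lg, function(l) mean(exp(-2 * w * l)),
                                          numeric(1)), "model")
    finite_size_correction(cm, T_obs)$mean_variance
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})
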