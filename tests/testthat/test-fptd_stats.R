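test_that("hysteresis extraction matches hand-traced cases", {
  rt <- extract_residence_times(c(-1, -1, 1, 1, 1, -1), dt = 1)
  expect_equal(rt$durations, 3)
  expect_equal(rt$censored_count, 2L)
  # monotone ramp crossing both thresholds once: both epochs censored
  ramp <- extract_residence_times(seq(-1, 1, length.out = 50), dt = 1)
  expect_length(ramp$durations, 0)
  expect_equal(ramp$censored_count, 2L)
  # no switches at all
  flat <- extract_residence_times(rep(-1, 10) + 0.01 * sin(1:10), dt = 1)
  expect_length(flat$durations, 0)
  expect_equal(flat$censored_count, 1L)
  # excursions that do not reach the far threshold do not switch the state
  wob <- extract_residence_times(c(-1, -0.2, 0.2, -1, 1, 1, -1, -1), dt = 1)
  expect_equal(wob$durations, 2)
})

test_that("telegraph dwell means follow the exponential closed form", {
  x <- generate_telegraph(0.02, duration = 6e5, dt = 1, seed = 8)
  r <- rle(as.integer(x))
  d <- r$lengths[-c(1, length(r$lengths))]
  expect_gt(length(d), 1e4)
  expect_equal(mean(d), 50, tolerance = 0.03)
})

test_that("log-binned pdf recovers closed-form densities and normalizes", {
  set.seed(5)
  pe <- log_binned_pdf(rexp(1e6), bins_per_decade = 8)
  sel <- pe$centers >= 0.1 & pe$centers <= 5
  expect_lt(max(abs(pe$density[sel] / exp(-pe$centers[sel]) - 1)), 0.05)
  # piecewise-constant integral is 1 by construction
  expect_equal(sum(pe$density * diff(pe$breaks)), 1, tolerance = 1e-9)
  # Pareto(alpha = 2): log-log slope -2 over the central decades
  set.seed(6)
  pp <- log_binned_pdf(1 / runif(1e6), bins_per_decade = 5)   # density t^-2
  sel <- pp$centers > 3 & pp$centers < 300 & pp$density > 0
  fit <- fit_loglog_slope(pp$centers[sel], pp$density[sel])
  expect_equal(fit$slope, -2, tolerance = 0.05)
})

test_that("power-law MLE recovers Pareto exponents and flags misfits", {
  set.seed(1)
  x <- 1 / runif(1e5)                       # Pareto density t^-2, xmin 1
  f <- fit_powerlaw_tail(x, xmin = 1, nboot = 50)
  expect_equal(f$exponent, -2, tolerance = 0.02)
  expect_true(f$ci[1] <= f$exponent & f$exponent <= f$ci[2])
  expect_gte(f$n_tail, 50)
  # truncated MLE is unbiased on bounded-Pareto draws
  set.seed(2)
  b <- -1; r <- 30
  tt <- (1 - runif(1e5) * (1 - r^b))^(1 / b)
  ft <- fit_powerlaw_tail(tt, xmin = 1, tmax = r, nboot = 0)
  expect_equal(ft$exponent, -2, tolerance = 0.03)
  # exponential data: the best fitted power law still misfits clearly,
  # with a KS distance far above the Pareto case at the same sample size
  set.seed(3)
  fe <- fit_powerlaw_tail(rexp(2e4) + 1, nboot = 0)
  set.seed(4)
  fp <- fit_powerlaw_tail(1 / runif(2e4), nboot = 0)
  expect_gt(fe$gof, 0.04)
  expect_gt(fe$gof, 5 * fp$gof)
  # degenerate input
  expect_error(fit_powerlaw_tail(rep(2, 100), nboot = 0))
  expect_error(fit_powerlaw_tail(1 / runif(100), xmin = -1), "positive")
})

test_that("exponential mixture EM recovers rates, weights, and nests", {
  set.seed(11)
  x1 <- rexp(1e5, rate = 2)
  m1 <- fit_exponential_mixture(x1, k = 1)
  expect_equal(m1$rates, 2, tolerance = 0.02)
  set.seed(12)
  x2 <- c(rexp(5e4, 1), rexp(5e4, 10))
  m2 <- fit_exponential_mixture(x2, k = 2)
  expect_equal(sort(m2$rates), c(1, 10), tolerance = 0.1)
  expect_equal(m2$weights, c(0.5, 0.5), tolerance = 0.05)
  m1b <- fit_exponential_mixture(x2, k = 1)
  expect_lt(m1b$loglik, m2$loglik)
})

test_that("FPTD mixture reduces to the single-rate law and integrates to 1", {
  w1 <- 0.37
  rd <- rate_distribution(omega_min = w1, omega_max = w1)
  tg <- seq(1e-4, 40, length.out = 8001)
  f <- fptd_mixture(rd, tg)
  # normalized over [t0, Inf): omega exp(-omega (t - t0)), pointwise to 1e-9
  expect_lt(max(abs(f - w1 * exp(-w1 * tg) / exp(-w1 * tg[1]))), 1e-9)
  # numerical normalization over [t0, Inf)
  num <- sum(diff(tg) * (head(f, -1) + tail(f, -1)) / 2) +
    exp(-w1 * max(tg)) / exp(-w1 * tg[1])     # analytic remainder
  expect_equal(num, 1, tolerance = 1e-6)
})

test_that("p(omega) ~ 1/omega produces the universal t^-2 mixture tail", {
  rd <- rate_distribution(function(w) 1 / w, 1e-4, 1)
  tg <- exp(seq(log(10), log(1e3), length.out = 30))
  f <- fptd_mixture(rd, tg)
  sl <- fit_loglog_slope(tg, f)
  expect_equal(sl$slope, -2, tolerance = 0.05)
})

test_that("Boltzmann-induced mixture matches the predicted exponent and gamma = beta + 2", {
  Tx <- 1e-3; Ts <- 1e-3
  pot <- double_well_potential(0)
  rd <- induced_rate_distribution(pot, Tx, Ts, omega0 = 1,
                                  omega_range = c(1e-9, exp(-2)))
  tg <- exp(seq(log(1e6), log(1e8), length.out = 25))
  beta <- fit_loglog_slope(tg, fptd_mixture(rd, tg, normalize = FALSE))$slope
  expect_equal(beta, asymptotic_exponent(Tx, Ts), tolerance = 0.1)
  gamma <- fit_loglog_slope(tg, mixture_correlation(rd, tg))$slope
  expect_equal(gamma - beta, 2, tolerance = 0.1)
})

test_that("asymptotic FPTD has the predicted limiting shapes", {
  pot <- double_well_potential(0)
  tg <- exp(seq(log(10), log(1e5), length.out = 40))
  # infinite slow noise: exactly t^-2
  expect_equal(asymptotic_fptd(pot, Tx = 1e-3, Ts = Inf, omega0 = 1, tg),
               tg^-2, tolerance = 1e-12)
  # quartic double well: slope -2 - Tx/(2 Ts)
  f <- asymptotic_fptd(pot, Tx = 0.1, Ts = 0.04, omega0 = 1, tg)
  expect_equal(fit_loglog_slope(tg, f)$slope, -2 - 0.1 / 0.08,
               tolerance = 1e-6)
  # doubling omega0 rescales by the closed-form constant 2^(-Tx/(2Ts))
  f2 <- asymptotic_fptd(pot, Tx = 0.1, Ts = 0.04, omega0 = 2, tg)
  expect_lt(max(abs(f2 / f - 2^(-0.1 / 0.08))), 1e-9)
  expect_error(asymptotic_fptd(pot, 0.1, 0.04, omega0 = 1, t_grid = c(0.5, 2)))
})

test_that("asymptotic exponent formula covers its limits", {
  expect_identical(asymptotic_exponent(1e-3, Inf), -2)
  expect_identical(asymptotic_exponent(0, 5), -2)
  expect_equal(asymptotic_exponent(1e-3, 5e-4, c = 0.5), -3)
  expect_error(asymptotic_exponent(1e-3, -1), "positive")
})

test_that("rate distributions validate normalization and support", {
  rd <- rate_distribution(function(w) w^2, 0.1, 3)
  expect_equal(integrate(rd$density, 0.1, 3)$value, 1, tolerance = 1e-6)
  expect_error(rate_distribution(function(w) w, -1, 2))
})
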