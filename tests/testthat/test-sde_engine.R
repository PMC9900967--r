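test_that("default potential has barrier deltaU = s^2 and consistent gradient", {
  pot <- double_well_potential()
  for (s in c(0.3, 1, 2.5)) {
    expect_equal(pot$U(0, s) - pot$U(1, s), s^2)
    expect_equal(pot$U(0, s) - pot$U(-1, s), s^2)
    expect_equal(pot$deltaU(s), s^2)
  }
  xg <- seq(-1.8, 1.8, by = 0.07)
  h <- 1e-4                               # balances truncation vs roundoff
  num <- (pot$U(xg + h, 1.3) - pot$U(xg - h, 1.3)) / (2 * h)
  ana <- pot$dUdx(xg, 1.3)
  away <- abs(ana) > 0.1                  # relative error defined off roots
  expect_lt(max(abs(num - ana)[away] / abs(ana)[away]), 1e-6)
})

test_that("parameter validation enforces stability and positivity", {
  expect_error(sde_params(Tx = 0.1, Ts = 0.1, tau_s = 10, T_expt = 1,
                          dt = 0.1), "tau_x / 50")
  expect_error(sde_params(Tx = 0.1, Ts = 0.1, tau_s = -1, T_expt = 1))
  expect_error(sde_params(Tx = 0.1, Ts = 0.1, tau_s = 10, T_expt = 1e-9,
                          dt = 1e-3), "T_expt")
})

test_that("noiseless descent relaxes monotonically into the well", {
  p <- sde_params(Tx = 0, Ts = 0, tau_s = Inf, mu_s = 1, T_expt = 8,
                  dt = 0.01)
  tr <- integrate_coupled(p, x0 = 0.5, s0 = 1)
  expect_true(all(diff(tr$x) >= 0))
  expect_equal(tail(tr$x, 1), 1, tolerance = 1e-5)
})

test_that("slow mode reaches the OU stationary law: variance Ts, ACF exp(-tau/tau_s)", {
  p <- sde_params(Tx = 0, Ts = 0.05, tau_s = 5, T_expt = 4000, dt = 0.01,
                  seed = 4)
  tr <- integrate_coupled(p, x0 = 1, s0 = 0.001, keep_every = 10L)
  s <- tr$s[-(1:500)]                       # discard transient
  expect_equal(var(s), 0.05, tolerance = 0.05)
  lag_t <- c(1, 2.5, 5)
  ac <- connected_acf_timeavg(s, tr$dt, max_lag = 6, lags = lag_t)
  idx <- match(lag_t, ac$lags)
  expect_equal(ac$values[idx], exp(-lag_t / 5), tolerance = 0.12)
})

test_that("integration is bitwise reproducible for a fixed seed", {
  p <- feasible_params(T_expt = 100, seed = 9)
  expect_identical(integrate_coupled(p)$x, integrate_coupled(p)$x)
  e1 <- sample_frozen_ensemble(p, n_real = 3)
  e2 <- sample_frozen_ensemble(p, n_real = 3)
  for (k in 1:3) expect_identical(e1[[k]]$x, e2[[k]]$x)
})

test_that("kramers_rate reproduces closed-form prefactors and monotonicity", {
  pot <- double_well_potential()
  # deltaU = Tx * ln 2 with fixed omega0 halves the attempt frequency
  expect_equal(kramers_rate(sqrt(log(2) * 0.3), pot, Tx = 0.3, omega0 = 7),
               3.5)
  # curvature prefactor at s = 1: sqrt(8 * 4) / (2 pi) = 2 sqrt(2) / pi
  expect_equal(kramers_rate(1, pot, Tx = 1) * exp(1), 2 * sqrt(2) / pi,
               tolerance = 1e-12)
  s <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(kramers_rate(s, pot, Tx = 0.1)) < 0))
  expect_error(kramers_rate(0, pot, Tx = 0.1), "barrier")
})

test_that("empirical escape rate agrees with Kramers within a factor 2", {
  tr <- frozen_dw_traj(T_expt = 5e4, seed = 12)     # deltaU/Tx = 5
  rt <- extract_residence_times(tr)
  expect_gt(length(rt$durations), 100)
  emp <- 1 / mean(rt$durations)
  kr <- kramers_rate(1, double_well_potential(1), 0.2)
  expect_lt(max(emp / kr, kr / emp), 2)
})

test_that("frozen ensemble draws s from the Boltzmann (Gaussian) weight", {
  p <- feasible_params(T_expt = 0.1, seed = 31, Ts = 0.02)
  ens <- sample_frozen_ensemble(p, n_real = 2000)
  s <- vapply(ens, function(tr) tr$s_frozen, numeric(1))
  ks <- ks.test(s, "pnorm", mean = 1, sd = sqrt(0.02))
  expect_gt(ks$p.value, 0.01)
  # Ts = 0 degenerates to s = mu_s for every realization
  p0 <- feasible_params(T_expt = 0.1, Ts = 0)
  s0 <- vapply(sample_frozen_ensemble(p0, n_real = 5),
               function(tr) tr$s_frozen, numeric(1))
  expect_identical(s0, rep(1, 5))
})

test_that("frozen-ensemble and fully coupled dwell distributions agree when tau_s >> T_expt", {
  n_real <- 24
  T_each <- 1e4
  pf <- feasible_params(T_expt = T_each, seed = 51, Ts = 0.02)
  ens <- sample_frozen_ensemble(pf, n_real = n_real)
  d_frozen <- unlist(lapply(ens, function(tr)
    extract_residence_times(tr)$durations))
  d_coupled <- unlist(lapply(seq_len(n_real), function(k) {
    pk <- sde_params(Tx = 0.2, Ts = 0.02, tau_s = 1e3 * T_each, mu_s = 1,
                     T_expt = T_each, dt = 0.01,
                     seed = slowmodes:::derive_seed(907, k))
    set.seed(pk$seed)
    s0 <- rnorm(1, 1, sqrt(0.02))
    extract_residence_times(integrate_coupled(pk, x0 = 1, s0 = s0))$durations
  }))
  expect_gt(length(d_frozen), 200)
  expect_gt(length(d_coupled), 200)
  expect_gt(suppressWarnings(ks.test(d_frozen, d_coupled))$p.value, 0.01)
})

test_that("halving dt changes the mean residence time by less than 5%", {
  m <- vapply(c(0.02, 0.01), function(dt) {
    p <- sde_params(Tx = 0.25, Ts = 0, tau_s = Inf, mu_s = 1, T_expt = 3e5,
                    dt = dt, seed = 71)
    mean(extract_residence_times(integrate_coupled(p, x0 = 1, s0 = 1))$durations)
  }, numeric(1))
  expect_lt(abs(m[1] - m[2]) / m[2], 0.05)
})

test_that("telegraph surrogate dwells match the direct SDE dwell distribution", {
  # same frozen barrier: SDE dwells should be exponential at ~the Kramers
  # rate, i.e. indistinguishable from the surrogate's telegraph dwells
  tr <- frozen_dw_traj(T_expt = 5e4, seed = 13)
  d_sde <- extract_residence_times(tr)$durations
  set.seed(14)
  tg <- slowmodes:::cpp_telegraph_dwells(1 / mean(d_sde), 1 / mean(d_sde),
                                         5e4 * 8, 0L)
  expect_gt(suppressWarnings(ks.test(d_sde, tg$durations))$p.value, 0.01)
})

test_that("poisson surrogate reproduces homogeneous closed forms", {
  ev <- poisson_surrogate(function(s) rep(0.05, length(s)),
                          numeric(2e6), dt = 1, seed = 3)
  gaps <- diff(ev)
  expect_gt(length(gaps), 5e4)
  expect_equal(mean(gaps), 20, tolerance = 0.02)
  expect_gt(suppressWarnings(ks.test(gaps, "pexp", rate = 0.05))$p.value,
            0.001)
  # zero rate everywhere: no events
  expect_length(poisson_surrogate(function(s) rep(0, length(s)),
                                  numeric(100), dt = 1), 0)
  expect_error(poisson_surrogate(function(s) rep(5, length(s)),
                                 numeric(100), dt = 1), "thinning")
})

test_that("frozen-rate ensemble tail is consistent with the asymptotic exponent", {
  # Kramers-telegraph surrogate vs the closed-form tail prediction
  Tx <- 1e-3
  p <- sde_params(Tx = Tx, Ts = 50 * Tx, tau_s = 1e10, T_expt = 1e7,
                  dt = 0.01, seed = 6)
  rk <- frozen_kramers_ensemble(p, n_real = 2000, min_keep = 1e3)
  expect_true(is.integer(rk$realization) || is.numeric(rk$realization))
  f <- fit_powerlaw_tail(rk$durations, xmin_range = c(3e4, 1e5),
                         tmax = 1e6, nboot = 0)
  expect_equal(f$exponent, asymptotic_exponent(Tx, 50 * Tx),
               tolerance = 0.2)
})
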