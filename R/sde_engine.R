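#' Parameters of the coupled fast/slow Langevin system
#'
#' The model separates a fast, ergodic coordinate `x` relaxing in a
#' multi-well landscape `U(x, s)` from a non-ergodic slow mode `s` that
#' modulates the landscape:
#' \deqn{dx = -\tau_x^{-1} \partial_x U(x, s)\,dt + \sqrt{2 T_x \tau_x^{-1}}\,dW_x,}
#' \deqn{ds = -\tau_s^{-1} \partial_s V(s)\,dt + \sqrt{2 T_s \tau_s^{-1}}\,dW_s,}
#' with independent Wiener increments. Time is measured in units of the fast
#' relaxation time, so `tau_x = 1` by default. `Tx` and `Ts` are the noise
#' levels of the fast and slow coordinates.
#'
#' @param Tx fast noise level (>= 0).
#' @param Ts slow noise level (>= 0).
#' @param tau_s slow relaxation time (> 0, may be `Inf` for a frozen mode).
#' @param T_expt total simulated duration.
#' @param mu_s slow-mode mean (default `Tx`, the worm-scale convention).
#' @param tau_x fast relaxation time (default 1).
#' @param dt integration step; must satisfy `dt <= tau_x / 50`.
#' @param seed integer master RNG seed.
#' @return An object of class `sde_params`.
#' @export
sde_params <- function(Tx, Ts, tau_s, T_expt, mu_s = Tx, tau_x = 1,
                       dt = 1e-3 * tau_x, seed = 1L) {
  stopifnot(is.numeric(Tx), Tx >= 0, is.numeric(Ts), Ts >= 0,
            is.numeric(tau_s), tau_s > 0, is.numeric(dt), dt > 0,
            is.numeric(tau_x), tau_x > 0, is.numeric(T_expt))
  if (dt > tau_x / 50)
    stop("dt must be <= tau_x / 50 for a stable Euler-Maruyama step")
  if (T_expt < dt) stop("T_expt must be at least dt")
  structure(list(Tx = Tx, Ts = Ts, tau_s = tau_s, mu_s = mu_s,
                 tau_x = tau_x, dt = dt, T_expt = T_expt,
                 seed = as.integer(seed)),
            class = "sde_params")
}

#' @export
print.sde_params <- function(x, ...) {
  cat("<sde_params> Tx =", x$Tx, " Ts =", x$Ts, " tau_s =", x$tau_s,
      " mu_s =", x$mu_s, "\n  tau_x =", x$tau_x, " dt =", x$dt,
      " T_expt =", x$T_expt, " seed =", x$seed, "\n")
  invisible(x)
}

#' Uniformly sampled trajectory container
#'
#' @param x numeric vector, fast coordinate.
#' @param dt sampling interval.
#' @param s optional slow-coordinate vector of equal length.
#' @param t0 start time.
#' @param params provenance, typically an [sde_params()].
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(x, dt, s = NULL, t0 = 0, params = NULL) {
  stopifnot(is.numeric(x), all(is.finite(x)), dt > 0)
  if (!is.null(s) && length(s) != length(x))
    stop("s must have the same length as x")
  structure(list(t0 = t0, dt = dt, x = as.numeric(x),
                 s = if (is.null(s)) NULL else as.numeric(s),
                 params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$x), "samples, dt =", x$dt,
      ", duration =", (length(x$x) - 1) * x$dt, "\n")
  invisible(x)
}

#' Integrate the coupled fast/slow Langevin system
#'
#' Fixed-step Euler-Maruyama integration of both equations with independent
#' noise streams for `x` and `s`. For the quartic double-well family the
#' inner loop is compiled; arbitrary [potential_spec()] objects fall back to
#' an R-level loop (use short runs there).
#'
#' @param params an [sde_params()].
#' @param potential a [potential_spec()]; default is the quartic double well
#'   with mean `params$mu_s`.
#' @param x0,s0 initial conditions (default: well minimum at `x = 1` and
#'   `s = mu_s`).
#' @param keep_every store every `keep_every`-th step (thinning for long
#'   runs); the returned trajectory has sampling interval `dt * keep_every`.
#' @return A [trajectory()] with both `x` and `s`.
#' @examples
#' p <- sde_params(Tx = 0.1, Ts = 0.01, tau_s = 100, T_expt = 10, dt = 0.01)
#' tr <- integrate_coupled(p)
#' @export
integrate_coupled <- function(params, potential = double_well_potential(params$mu_s),
                              x0 = 1, s0 = params$mu_s, keep_every = 1L) {
  stopifnot(inherits(params, "sde_params"), inherits(potential, "potential_spec"))
  n_steps <- floor(params$T_expt / params$dt)
  set.seed(params$seed)
  if (identical(potential$kind, "quartic_double_well")) {
    res <- cpp_em_coupled(n_steps, as.integer(keep_every), params$dt,
                          params$Tx, params$Ts, params$tau_s, params$tau_x,
                          x0, s0, params$mu_s, 0)
    if (res$bad_step > 0)
      stop("non-finite state at step ", res$bad_step,
           "; the integration step dt is likely too large")
    return(trajectory(res$x, params$dt * keep_every, s = res$s,
                      params = params))
  }
  em_coupled_r(params, potential, x0, s0, n_steps, keep_every)
}

# Reference R integrator for arbitrary potentials; slow drift from a central
# difference of V so custom slow-mode potentials need no analytic gradient.
em_coupled_r <- function(params, potential, x0, s0, n_steps, keep_every) {
  dt <- params$dt
  sig_x <- sqrt(2 * params$Tx * dt / params$tau_x)
  sig_s <- if (params$Ts > 0 && is.finite(params$tau_s))
    sqrt(2 * params$Ts * dt / params$tau_s) else 0
  h <- 1e-6 * max(1, abs(s0))
  dVds <- function(s) (potential$V(s + h) - potential$V(s - h)) / (2 * h)
  nk <- n_steps %/% keep_every + 1
  xs <- numeric(nk); ss <- numeric(nk)
  x <- x0; s <- s0; xs[1] <- x; ss[1] <- s; k <- 2L
  zx <- rnorm(n_steps); zs <- rnorm(n_steps)
  for (i in seq_len(n_steps)) {
    fx <- -potential$dUdx(x, s) / params$tau_x
    fs <- if (is.finite(params$tau_s)) -dVds(s) / params$tau_s else 0
    x <- x + fx * dt + sig_x * zx[i]
    s <- s + fs * dt + sig_s * zs[i]
    if (!is.finite(x) || !is.finite(s))
      stop("non-finite state at step ", i,
           "; the integration step dt is likely too large")
    if (i %% keep_every == 0) { xs[k] <- x; ss[k] <- s; k <- k + 1L }
  }
  trajectory(xs, dt * keep_every, s = ss, params = params)
}

# Draw n samples of s from the Boltzmann weight exp(-V(s)/Ts). Quadratic V
# gives a Gaussian; other potentials are sampled by inverse-CDF on a grid.
sample_boltzmann_s <- function(potential, Ts, n, mu_s = potential$mu_s) {
  if (Ts == 0) return(rep(mu_s, n))
  if (identical(potential$kind, "quartic_double_well"))
    return(rnorm(n, mean = mu_s, sd = sqrt(Ts)))
  half <- 12 * sqrt(Ts) + abs(mu_s)
  sg <- seq(mu_s - half, mu_s + half, length.out = 20001)
  w <- exp(-(potential$V(sg) - min(potential$V(sg))) / Ts)
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], sg[keep], xout = runif(n), rule = 2)$y
}

#' Frozen slow-mode ensemble of trajectories
#'
#' In the regime `tau_s >> T_expt` each realization experiences an
#' effectively constant slow mode. This function draws `s` once per
#' realization from the Boltzmann weight `exp(-V(s)/Ts)` (a Gaussian with
#' mean `mu_s` and variance `Ts` for the default quadratic `V`), freezes it,
#' and integrates the fast coordinate. Per-realization seeds are derived
#' deterministically from the master seed, so the ensemble is reproducible
#' and order-independent.
#'
#' With `Ts = 0` every realization uses `s = mu_s` (degenerate but valid).
#'
#' @inheritParams integrate_coupled
#' @param n_real number of realizations (>= 1).
#' @return A list of [trajectory()] objects (class `trajectory_ensemble`);
#'   each carries its frozen `s` value.
#' @export
sample_frozen_ensemble <- function(params, potential = double_well_potential(params$mu_s),
                                   n_real, x0 = 1, keep_every = 1L) {
  stopifnot(inherits(params, "sde_params"), n_real >= 1)
  if (is.finite(params$tau_s) && params$tau_s < 10 * params$T_expt)
    warning("tau_s is not large compared to T_expt; the frozen-s ensemble ",
            "approximation may be poor")
  n_steps <- floor(params$T_expt / params$dt)
  out <- vector("list", n_real)
  for (k in seq_len(n_real)) {
    sk <- derive_seed(params$seed, k)
    set.seed(sk)
    s_frozen <- sample_boltzmann_s(potential, params$Ts, 1, params$mu_s)
    if (identical(potential$kind, "quartic_double_well")) {
      res <- cpp_em_coupled(n_steps, as.integer(keep_every), params$dt,
                            params$Tx, 0, Inf, params$tau_x,
                            x0, s_frozen, params$mu_s, 0)
      if (res$bad_step > 0)
        stop("non-finite state at step ", res$bad_step, " (realization ", k, ")")
      tr <- trajectory(res$x, params$dt * keep_every, s = res$s, params = params)
    } else {
      pk <- params; pk$Ts <- 0; pk$tau_s <- Inf
      tr <- em_coupled_r(pk, potential, x0, s_frozen, n_steps, keep_every)
    }
    tr$s_frozen <- s_frozen
    tr$seed <- sk
    out[[k]] <- tr
  }
  structure(out, class = c("trajectory_ensemble", "list"), params = params)
}

#' Kramers escape rate from a well of the modulated landscape
#'
#' Returns the overdamped Kramers rate
#' \deqn{\omega(s) = \omega_0(s) \exp(-\Delta U(s) / T_x),}
#' with the prefactor computed from the curvatures at the well minimum and
#' barrier top, \eqn{\omega_0 = \sqrt{U''_{min} |U''_{max}|} / (2\pi)}, unless
#' a constant `omega0` is supplied. For the default quartic double well
#' `omega0(s) = (2 sqrt(2) / pi) s^2`.
#'
#' @param s slow-mode value(s); vectorized.
#' @param potential a [potential_spec()].
#' @param Tx fast noise level (> 0).
#' @param omega0 optional constant attempt frequency overriding the
#'   curvature-based prefactor.
#' @return Positive escape rate(s).
#' @export
kramers_rate <- function(s, potential = double_well_potential(), Tx, omega0 = NULL) {
  stopifnot(Tx > 0)
  dU <- potential$deltaU(s)
  if (any(dU <= 0)) stop("deltaU(s) must be positive: no barrier to escape over")
  w0 <- if (is.null(omega0)) {
    sqrt(potential$curvature_min(s) * abs(potential$curvature_barrier(s))) / (2 * pi)
  } else rep_len(omega0, length(s))
  w0 * exp(-dU / Tx)
}

#' Inhomogeneous Poisson surrogate of barrier-crossing events
#'
#' Simulates escape events as an inhomogeneous Poisson process whose rate
#' follows the slow-mode path through a rate mapping (typically
#' [kramers_rate()]), using thinning against the maximal rate. Inter-event
#' times are surrogate first-passage times; this is the standard light-weight
#' check of the heavy-tail predictions, since it bypasses the microscopic
#' barrier-crossing dynamics.
#'
#' @param rate_of_s function mapping slow-mode values to escape rates.
#' @param s_path numeric vector, slow-mode path sampled every `dt`.
#' @param dt sampling interval of `s_path`.
#' @param seed integer RNG seed.
#' @return Numeric vector of event times in `[0, length(s_path) * dt)`.
#' @export
poisson_surrogate <- function(rate_of_s, s_path, dt, seed = 1L) {
  rates <- rate_of_s(s_path)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates along the path must be positive and finite")
  if (max(rates) * dt > 0.1)
    stop("max(rate) * dt exceeds 0.1: thinning resolution insufficient, ",
         "reduce dt")
  set.seed(seed)
  cpp_poisson_thinning(rates, dt)
}

#' Frozen-rate Kramers ensemble of residence times
#'
#' The event-level counterpart of [sample_frozen_ensemble()]: each
#' realization draws a frozen slow-mode value from the Boltzmann weight,
#' converts it to a hopping rate via [kramers_rate()], and simulates a
#' symmetric two-state telegraph process over `T_expt`, whose complete dwell
#' times are the surrogate residence times. Because only barrier-crossing
#' events are simulated, ensembles deep in the Kramers regime (tiny `Tx`,
#' rates far below the fast relaxation rate) are accessible at a cost
#' proportional to the number of events rather than the number of
#' integration steps. High-rate realizations contribute proportionally more
#' dwells, which reproduces the transition-count weighting of the
#' first-passage-time mixture.
#'
#' @inheritParams sample_frozen_ensemble
#' @param omega0 optional constant attempt frequency passed to
#'   [kramers_rate()].
#' @param min_keep dwells shorter than this are dropped from the pooled
#'   vector (but still counted in `n_total`); use when only the far tail is
#'   needed and the full event list would be large.
#' @param barrier_min Kramers-validity threshold in units of `Tx`: frozen
#'   slow-mode draws with barrier `deltaU(s) < barrier_min * Tx` are outside
#'   the Kramers regime (their true hopping is fast, barrier-free diffusion,
#'   not the vanishing curvature-limited Kramers value) and are redrawn, so
#'   the ensemble is Boltzmann *conditioned on the Kramers regime*. These
#'   rejected realizations would only populate the short-time bulk; the
#'   asymptotic tail, which is what this ensemble is built to measure, is
#'   carried entirely by the high-barrier draws. Default 2.
#' @return A [residence_times()] object pooling all complete dwells, with
#'   fields `s` and `omega` (per-realization frozen values and rates) and
#'   `n_real`, `n_total`, `T_expt` attached.
#' @export
frozen_kramers_ensemble <- function(params, potential = double_well_potential(params$mu_s),
                                    n_real, omega0 = NULL, min_keep = 0,
                                    barrier_min = 2) {
  stopifnot(inherits(params, "sde_params"), n_real >= 1)
  dur <- vector("list", n_real)
  svals <- numeric(n_real); om <- numeric(n_real)
  censored <- 0L; n_total <- 0
  for (k in seq_len(n_real)) {
    set.seed(derive_seed(params$seed, k))
    s <- draw_kramers_regime_s(potential, params, barrier_min)
    w <- kramers_rate(s, potential, params$Tx, omega0)
    svals[k] <- s; om[k] <- w
    if (!is.finite(w) || w * params$T_expt < 1e-12) { censored <- censored + 1L; next }
    tg <- cpp_telegraph_dwells(w, w, params$T_expt, 0L)
    n_total <- n_total + length(tg$durations)
    dur[[k]] <- if (min_keep > 0) tg$durations[tg$durations >= min_keep]
      else tg$durations
    censored <- censored + tg$censored
  }
  ids <- rep.int(seq_len(n_real), lengths(dur))
  rt <- residence_times(unlist(dur), censored_count = censored,
                        min_duration = 0, realization = ids)
  rt$s <- svals; rt$omega <- om
  rt$n_real <- n_real; rt$n_total <- n_total
  rt$T_expt <- params$T_expt; rt$params <- params
  rt
}

#' Ensemble non-connected correlation of the frozen-rate surrogate
#'
#' Companion of [frozen_kramers_ensemble()] for correlation tails: each
#' realization is a symmetric telegraph process in `x = +/-1` at its frozen
#' Kramers rate, sampled every `dt_obs`, and the non-connected
#' autocorrelation `<x(t) x(t+tau)>` is accumulated across realizations
#' without storing the ensemble. Realizations whose rate is negligible on
#' the observation window contribute the constant value 1, as they should:
#' a frozen particle never decorrelates within the window.
#'
# Boltzmann draw of the frozen slow mode conditioned on the Kramers regime
# deltaU(s) >= barrier_min * Tx (see frozen_kramers_ensemble). Deterministic
# given the RNG state; errors out if the regime has negligible mass.
draw_kramers_regime_s <- function(potential, params, barrier_min) {
  thr <- barrier_min * params$Tx
  for (i in 1:100000) {
    s <- sample_boltzmann_s(potential, params$Ts, 1, params$mu_s)
    if (potential$deltaU(s) >= thr) return(s)
  }
  stop("Kramers regime deltaU >= ", barrier_min,
       " * Tx has negligible Boltzmann mass at these parameters")
}

#' @inheritParams frozen_kramers_ensemble
#' @param dt_obs sampling interval of the telegraph series; must resolve
#'   the fastest rate (`2 * max(omega) * dt_obs < 0.5`).
#' @param lags lag grid in time units (multiples of `dt_obs`); default 60
#'   log-spaced lags up to `max_lag`.
#' @param max_lag largest lag (default `T_expt / 10`).
#' @return A [correlation_estimate()] (estimator `nonconnected_ensemble`),
#'   normalized at the first positive lag.
#' @export
frozen_kramers_correlation <- function(params, potential = double_well_potential(params$mu_s),
                                       n_real, dt_obs, omega0 = NULL,
                                       lags = NULL, max_lag = params$T_expt / 10,
                                       barrier_min = 2) {
  stopifnot(inherits(params, "sde_params"), n_real >= 2)
  n <- floor(params$T_expt / dt_obs)
  if (is.null(lags)) {
    L <- unique(round(exp(seq(log(1), log(max_lag / dt_obs), length.out = 60))))
  } else {
    L <- sort(unique(as.integer(round(lags / dt_obs))))
  }
  L <- L[L >= 1 & L < n]
  acc <- numeric(length(L))
  for (k in seq_len(n_real)) {
    set.seed(derive_seed(params$seed, k))
    s <- draw_kramers_regime_s(potential, params, barrier_min)
    w <- kramers_rate(s, potential, params$Tx, omega0)
    if (!is.finite(w)) w <- 0
    if (2 * w * dt_obs >= 0.5)
      stop("dt_obs too coarse for the fastest sampled rate")
    if (w * params$T_expt < 1e-8) {     # frozen within the window
      acc <- acc + 1
      next
    }
    st <- cpp_telegraph_sample(w, w, n, dt_obs, if (runif(1) < 0.5) 0L else 1L)
    x <- 2 * st - 1
    acc <- acc + cpp_acf_lags(as.numeric(x), L, FALSE)
  }
  vals <- acc / n_real
  vals <- vals / vals[1]
  correlation_estimate(L * dt_obs, vals, "nonconnected_ensemble",
                       n_series = n_real, T_obs = (n - 1) * dt_obs)
}
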