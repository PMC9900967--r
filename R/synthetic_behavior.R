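#' Slow adaptation schedule for synthetic behavior
#'
#' Describes how the slow parameters of the landscape drift over an
#' observation window: the slow-mode mean `mu_s(t)` and/or a well-asymmetry
#' tilt `a(t)` added to the potential as `-a(t) x` (a positive tilt deepens
#' the `x = +1` well). The `constant` schedule reproduces the stationary
#' model exactly; `linear` interpolates between start and end values;
#' `ou_path` lets `mu_s` itself follow an Ornstein-Uhlenbeck path with
#' timescale `ou_tau` and level `ou_T` (seeded independently of the
#' integration noise).
#'
#' @param kind `"constant"`, `"linear"`, or `"ou_path"`.
#' @param mu_s baseline slow-mode mean (start value for `linear`/`ou_path`).
#' @param mu_s_end final mean for `linear`.
#' @param tilt,tilt_end start and end well-asymmetry tilt.
#' @param ou_tau,ou_T OU timescale and noise level for `ou_path`.
#' @param seed RNG seed for `ou_path`.
#' @return An object of class `adaptation_schedule`.
#' @export
adaptation_schedule <- function(kind = c("constant", "linear", "ou_path"),
                                mu_s = 0, mu_s_end = mu_s,
                                tilt = 0, tilt_end = tilt,
                                ou_tau = NULL, ou_T = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "ou_path") stopifnot(!is.null(ou_tau), ou_tau > 0,
                                   !is.null(ou_T), ou_T >= 0)
  structure(list(kind = kind, mu_s = mu_s, mu_s_end = mu_s_end,
                 tilt = tilt, tilt_end = tilt_end,
                 ou_tau = ou_tau, ou_T = ou_T, seed = as.integer(seed)),
            class = "adaptation_schedule")
}

# Evaluate the schedule on the integration grid. Returns length-1 vectors
# for parameters that are constant (the compiled integrator broadcasts).
schedule_paths <- function(schedule, n_steps, dt) {
  s <- schedule
  tfrac <- (seq_len(n_steps) - 1) / max(n_steps - 1, 1)
  mu <- switch(s$kind,
    constant = s$mu_s,
    linear = s$mu_s + (s$mu_s_end - s$mu_s) * tfrac,
    ou_path = {
      set.seed(derive_seed(s$seed, 104729L))
      path <- cpp_em_ou(n_steps, 1L, dt, s$ou_tau, s$mu_s, s$ou_T, s$mu_s)
      path[seq_len(n_steps)]
    })
  a <- if (s$kind == "linear" && s$tilt_end != s$tilt)
    s$tilt + (s$tilt_end - s$tilt) * tfrac else s$tilt
  list(mu_s = mu, tilt = a)
}

#' Generate an adapting double-well dataset with ground truth
#'
#' Integrates the coupled fast/slow system with schedule-modulated
#' parameters and records the full ground truth (fast and slow paths, the
#' schedule, two-state labels from the +/-0.5 hysteresis rule, and every
#' generator parameter), so inference pipelines can be validated without
#' any external data. A constant schedule is statistically identical to
#' [integrate_coupled()].
#'
#' @inheritParams integrate_coupled
#' @param schedule an [adaptation_schedule()].
#' @return List with `trajectory` (a [trajectory()]) and `ground_truth`
#'   (list with `x`, `s`, `labels`, `schedule`, `params`, `manifest`).
#' @export
generate_adapting_double_well <- function(params, schedule,
                                          x0 = 1, s0 = NULL,
                                          keep_every = 1L) {
  stopifnot(inherits(params, "sde_params"),
            inherits(schedule, "adaptation_schedule"))
  n_steps <- floor(params$T_expt / params$dt)
  paths <- schedule_paths(schedule, n_steps, params$dt)
  s0 <- s0 %||% paths$mu_s[1]
  set.seed(params$seed)
  res <- cpp_em_coupled(n_steps, as.integer(keep_every), params$dt,
                        params$Tx, params$Ts, params$tau_s, params$tau_x,
                        x0, s0, paths$mu_s, paths$tilt)
  if (res$bad_step > 0)
    stop("non-finite state at step ", res$bad_step,
         "; the integration step dt is likely too large")
  tr <- trajectory(res$x, params$dt * keep_every, s = res$s, params = params)
  labels <- hysteresis_states(tr$x, -0.5, 0.5)
  manifest <- list(generator = "generate_adapting_double_well",
                   params = unclass(params),
                   schedule = unclass(schedule),
                   x0 = x0, s0 = s0, keep_every = keep_every)
  list(trajectory = tr,
       ground_truth = list(x = tr$x, s = tr$s, labels = labels,
                           schedule = schedule, params = params,
                           manifest = manifest))
}

#' Posture-like multichannel observations of a slow coordinate
#'
#' Embeds the scalar slow coordinate into `n_channels` observed channels by
#' a fixed random orthonormal mixing of `[x, fast OU channels]`, emulating
#' high-dimensional posture-like measurements in which the slow mode is
#' linearly recoverable. The fast channels have time constant
#' `0.05 * tau_x` so they are clearly sub-dominant in timescale.
#'
#' @param traj a [trajectory()] carrying the slow coordinate in `x`.
#' @param n_channels number of observed channels (>= 2).
#' @param fast_noise_scale standard deviation of the fast channels relative
#'   to the standardized slow coordinate.
#' @param seed RNG seed (mixing matrix and fast channels).
#' @return Numeric matrix (time x channels) with attributes `mixing` (the
#'   orthonormal matrix) and `manifest`.
#' @export
generate_posturelike_channels <- function(traj, n_channels,
                                          fast_noise_scale = 1, seed = 1L) {
  stopifnot(inherits(traj, "trajectory"), n_channels >= 2)
  n <- length(traj$x)
  tau_fast <- 0.05 * (traj$params$tau_x %||% 1)
  set.seed(derive_seed(seed, 7L))
  Q <- qr.Q(qr(matrix(rnorm(n_channels^2), n_channels)))
  z <- (traj$x - mean(traj$x)) / sd(traj$x)
  ke <- max(1L, as.integer(ceiling(traj$dt / (tau_fast / 10))))
  dt_sim <- traj$dt / ke
  fast <- sapply(seq_len(n_channels - 1), function(j) {
    set.seed(derive_seed(seed, 100L + j))
    f <- cpp_em_ou((n - 1) * ke, ke, dt_sim, tau_fast, 0, 1, 0)
    fast_noise_scale * f[seq_len(n)]
  })
  src <- cbind(z, fast)
  out <- src %*% t(Q)
  attr(out, "mixing") <- Q
  attr(out, "manifest") <- list(generator = "generate_posturelike_channels",
                                n_channels = n_channels,
                                fast_noise_scale = fast_noise_scale,
                                tau_fast = tau_fast, seed = seed)
  out
}

#' Two-state telegraph process sampled on a regular grid
#'
#' Continuous-time two-state Markov chain (the minimal model of metastable
#' hopping) simulated event-by-event and sampled every `dt`. The initial
#' state is drawn from the stationary distribution.
#'
#' @param rates positive switching rate(s): a single symmetric rate or
#'   `c(rate01, rate10)`; `max(rate) * dt` must stay below 0.1.
#' @param duration total duration; shorter than `dt` gives an empty
#'   sequence.
#' @param dt sampling interval.
#' @param seed RNG seed.
#' @return Integer vector of states (0/1) with attribute `manifest`.
#' @export
generate_telegraph <- function(rates, duration, dt, seed = 1L) {
  rates <- rep_len(as.numeric(rates), 2)
  stopifnot(all(rates > 0))
  if (max(rates) * dt >= 0.1)
    stop("rate * dt must be below 0.1; reduce dt")
  n <- floor(duration / dt)
  if (n < 1) return(structure(integer(0), manifest = list(rates = rates,
                                                          duration = duration,
                                                          dt = dt, seed = seed)))
  set.seed(seed)
  p1 <- rates[1] / sum(rates)   # stationary probability of state 1
  s0 <- as.integer(runif(1) < p1)
  out <- cpp_telegraph_sample(rates[1], rates[2], n, dt, s0)
  structure(out, manifest = list(generator = "generate_telegraph",
                                 rates = rates, duration = duration,
                                 dt = dt, seed = seed, state0 = s0))
}
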