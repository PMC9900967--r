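# Shared fixtures: all synthetic, built in code at test time.

# A feasible Kramers regime for direct SDE runs: barrier deltaU/Tx = 5
# at s = 1 gives escape rate ~6e-3/tau_x, so thousands of hops fit in a
# short simulation.
feasible_params <- function(T_expt = 2e4, seed = 1L, Tx = 0.2, Ts = 0.02,
                            tau_s = 1e9, dt = 0.01) {
  sde_params(Tx = Tx, Ts = Ts, tau_s = tau_s, mu_s = 1, T_expt = T_expt,
             dt = dt, seed = seed)
}

# Long frozen double-well trajectory at s = 1 (hops at ~6e-3/tau_x).
frozen_dw_traj <- function(T_expt = 2e4, seed = 2L, Tx = 0.2, dt = 0.01,
                           keep_every = 1L) {
  p <- sde_params(Tx = Tx, Ts = 0, tau_s = Inf, mu_s = 1, T_expt = T_expt,
                  dt = dt, seed = seed)
  integrate_coupled(p, x0 = 1, s0 = 1, keep_every = keep_every)
}

# Exact OU sampler used as an independent oracle (exact discretization,
# not Euler): x_{t+1} = a x_t + sqrt(D (1 - a^2) / theta) z.
ou_exact <- function(n, dt, theta = 1, D = 0.5, x0 = NULL, seed = 1L) {
  set.seed(seed)
  a <- exp(-theta * dt)
  sd_stat <- sqrt(D / theta)
  x <- numeric(n)
  x[1] <- x0 %||% rnorm(1, 0, sd_stat)
  innov <- rnorm(n - 1, 0, sd_stat * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i - 1]
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
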