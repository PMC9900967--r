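---
title: "Heavy tails from slowly fluctuating landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy tails from slowly fluctuating landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowmodes)
```

## The model

Long recordings of animal behavior typically show fast, stereotyped
movements organized into a few long-lived states, with stochastic
transitions between them. `slowmodes` treats this as overdamped Langevin
motion of a fast coordinate $x$ in a multi-well landscape whose shape is
modulated by a slow, non-ergodic mode $s$:

$$dx = -\tau_x^{-1}\,\partial_x U(x,s)\,dt + \sqrt{2 T_x \tau_x^{-1}}\,dW_x,
\qquad
ds = -\tau_s^{-1}\,\partial_s V(s)\,dt + \sqrt{2 T_s \tau_s^{-1}}\,dW_s,$$

with time in units of the fast relaxation time ($\tau_x = 1$). The default
landscape is the quartic double well $U(x,s) = s^2 (x^2-1)^2$ with
$V(s) = (s-\mu_s)^2/2$: wells at $x = \pm 1$ represent two metastable
behavioral states, and the barrier height $\Delta U(s) = s^2$ is set by
the slow mode. The key regime is $\tau_s \sim T_{\mathrm{expt}}$ or
larger: the slow mode does not equilibrate within one recording, so each
recording (or each animal) effectively experiences its own landscape.

Escapes from a well occur at the Kramers rate
$\omega(s) = \omega_0(s)\, e^{-\Delta U(s)/T_x}$ with the overdamped
prefactor $\omega_0 = \sqrt{U''_{\min} |U''_{\max}|}/2\pi$
(`kramers_rate()`; a constant user-supplied $\omega_0$ is also accepted,
and is the convention in which the tail asymptotics below are cleanest).
When the slow mode is frozen and Boltzmann-distributed,
$p(s) \propto e^{-V(s)/T_s}$, the pooled residence-time density is a
rate mixture weighted by the number of transitions each rate contributes,
$f(t) \propto \int p(\omega)\,\omega\cdot\omega e^{-\omega t}\,d\omega$
(`fptd_mixture()`), whose large-$t$ behavior is

$$f(t) \sim t^{-2}\, \exp\!\left[-V\!\big(\Delta U^{-1}(T_x \ln \omega_0
t)\big)/T_s\right]$$

(`asymptotic_fptd()`). For $V$ and $\Delta U$ asymptotically equivalent
this is a power law $t^{-2 - c\,T_x/T_s}$, with $c = 1/2$ for the default
landscape (`asymptotic_exponent()`), approaching the universal $t^{-2}$
as $T_s \to \infty$. The non-connected correlation function obeys the
same asymptotics without the $t^{-2}$ factor, so the two tail exponents
differ by exactly 2 (`asymptotic_correlation()`, `mixture_correlation()`).

## Simulation engines and their regimes

`integrate_coupled()` is a fixed-step Euler--Maruyama integrator
(compiled, independent noise streams for $x$ and $s$; default
`dt = 1e-3` with a hard cap `dt <= tau_x/50`). Additive noise makes weak
order 1 sufficient for the distributional quantities this package
targets; the suite verifies that halving `dt` moves mean residence times
by less than 5%.

Direct integration resolves the fast dynamics, so its cost per escape is
$\mathcal{O}(1/(\omega\,dt))$ steps. At the headline study conditions
($T_x = 10^{-3}$) the fastest Kramers rate across the Boltzmann ensemble
is $\approx 3\times 10^{-4}/\tau_x$, and the asymptotic tail only opens
up for observation windows of $10^7\,\tau_x$ and beyond: brute force is
out of reach at desk scale. Two ensemble engines avoid this:

* `sample_frozen_ensemble()` freezes $s$ per realization (valid when
  $\tau_s \gg T_{\mathrm{expt}}$) and integrates $x$ directly. Used at
  feasible barriers (e.g. $T_x = 0.2$, $\Delta U/T_x = 5$), it is the
  ground truth the surrogates are tested against.
* `frozen_kramers_ensemble()` / `frozen_kramers_correlation()` replace
  the microscopic dynamics by a symmetric telegraph process at the frozen
  Kramers rate (event-level simulation; cost proportional to the number
  of transitions). Pooling complete dwells across realizations
  automatically reproduces the transition-count weighting of the mixture
  density. The test suite checks that telegraph dwells and direct-SDE
  dwells from the same frozen barrier are statistically
  indistinguishable, and `poisson_surrogate()` provides the
  inhomogeneous-rate analogue by thinning.

**Kramers-regime conditioning.** The curvature prefactor
$\omega_0(s) \propto s^2$ vanishes as $s \to 0$, which would assign
absurdly slow rates to realizations with *no* barrier -- in the true
dynamics those cross at the fast, barrier-free diffusion rate and
populate only the short-time bulk. The ensemble engines therefore redraw
slow-mode values until $\Delta U(s) \ge 2 T_x$ (argument `barrier_min`),
i.e. they sample the Boltzmann weight conditioned on the Kramers regime.
This leaves the asymptotic tail -- the object of interest -- untouched.

## Estimators

**Residence times.** `extract_residence_times()` uses two-threshold
hysteresis (defaults $\mp 0.5$ for wells at $\pm 1$): the state switches
only at the far threshold, which suppresses the double counting a single
zero-crossing rule produces under within-well noise. Boundary-censored
intervals are excluded and counted, not modeled; survival-type handling
is deliberately out of scope.

**Tail exponents.** `fit_powerlaw_tail()` implements the continuous
Pareto MLE with KS-minimizing cutoff selection. Two refinements matter in
this problem and are validated in the suite:

* *Truncation.* The observation window censors dwells near
  $T_{\mathrm{expt}}$; fitting the unbounded Pareto to window-limited
  data biases the exponent steep. With `tmax` set, the likelihood of the
  power law truncated to `[xmin, tmax]` is maximized instead (verified
  unbiased on exact bounded-Pareto draws). Fit windows are kept inside
  $[\,t_{\mathrm{bulk}},\, 0.1\,T_{\mathrm{expt}}]$, where
  $t_{\mathrm{bulk}}$ is the point at which the exponential bulk of the
  mixture has decayed below a few percent (computable from the rate
  distribution by quadrature).
* *Log corrections.* For a Gaussian slow mode mapped through a
  constant-$\omega_0$ Kramers rate, the change of variables contributes
  an exact factor $1/\sqrt{\ln(\omega_0/\omega)}$ to $p(\omega)$, so the
  dwell density is $t^{-\alpha}/\sqrt{\ln \omega_0 t}$ rather than pure
  Pareto; the pure MLE is then biased steep by
  $\approx 1/(2\ln \omega_0 t)$, which decays only logarithmically and
  never becomes negligible at feasible depths.
  `fit_asymptotic_tail()` fits the corrected family and recovers the
  asymptotic exponent without that bias. Its confidence intervals
  resample whole realizations, because dwells within one frozen
  realization share a rate and a dwell-level bootstrap understates the
  ensemble variance severely.

**Correlation functions.** `connected_acf_timeavg()` subtracts the
per-series sample mean (the per-animal estimator a finite recording
permits) and averages across series; `nonconnected_acf_ensemble()`
averages raw products across an ensemble and normalizes at the first
reported lag. Both work on explicit lag grids in the lag domain; there is
deliberately no spectral path.

**Finite-size anti-correlations.** Over a window $T$ the sample mean
differs from the ensemble mean, biasing the connected estimator negative
at large lags. With $m(t) = \mathrm{Cov}(x_t, \hat\mu)$,
`finite_size_correction()` evaluates the exact second-order expectation
$E[\hat C(\tau)] = C(\tau) - \mathrm{avg}_t[m(t) + m(t+\tau)] +
\mathrm{Var}(\hat\mu)$ on the model grid. The first-order form
$C(\tau) - \mathrm{Var}(\hat\mu)$ (kept as `method = "mean_variance"`)
misses a 2000-replicate Monte-Carlo oracle by more than 10 standard
errors at small lags; the exact form agrees within 1 SE at all tested
lags. Predictions are made at the *covariance* level: the
variance-normalized estimator carries an additional small ratio bias
that is not modeled.

**Langevin inference.** `estimate_drift_diffusion()` performs
*local-linear* kernel regression (Epanechnikov weights, Silverman-type
default bandwidth) of the first two conditional moments of increments
over the Markov--Einstein interval $\tau^*$; local-linear fits cancel
the density-gradient bias of a local-constant smoother, and the
diffusion uses the residual variance about the local fit (first-order
drift correction). Pointwise drift errors scale with the observed time
span, not the number of samples. `select_markov_einstein_time()` picks
the smallest candidate $\tau^*$ whose standardized increment residuals
have lag-1 autocorrelation below 0.05. `estimate_time_dependent()`
applies the same estimator on overlapping windows (default 10 windows at
50% overlap) that tile the record, with the final window anchored at the
end; `simulate_km_model()` resimulates inferred models with linear
interpolation in $x$, piecewise-constant coefficients in time, and
reflecting boundaries at the grid edges, since inferred coefficients are
meaningless outside the sampled range.

**State-space pipeline.** `delay_embed()` restores approximate
Markovianity by stacking recent frames; `cluster_microstates()` (k-means,
fixed seed, 10 restarts; default 100 microstates) discretizes the
embedded space; `transition_matrix()` and `spectral_decomposition()`
build the transfer-operator matrix and its spectrum (computed on the
row-stochastic matrix, leading eigenvalue 1; generator-convention
timescales are recovered as $t_i = -\tau/\ln|\Lambda_i|$).
`project_phi2()` maps frames onto the first non-trivial right
eigenvector with the sign fixed so the longer-lived coarse state is
negative, and `split_two_states()` chooses the two-state threshold by
maximizing the coarse metastability score (the trace of the 2x2
transition matrix, near 2 for clean metastability and near 1 for noise),
ties broken toward the series median. Presets: depth 11 and
$\tau^* = 0.75$ s at 1/16 s sampling for crawling-worm-like data; depth
5 and $\tau^* = 3$ events for bout-structured swimming data.

## The synthetic-data generators

`generate_adapting_double_well()` produces the package's reference
datasets: the coupled system with schedule-modulated parameters
(`adaptation_schedule()`: constant, linear drift of the slow mean and/or
a well-asymmetry tilt $-a(t)x$, or an Ornstein--Uhlenbeck path for the
slow mean), with complete ground truth (paths, hysteresis labels,
parameters) recorded. Adaptation is modeled as one well deepening over
time while the barrier stays near the origin, matching the phenomenology
the analysis is meant to recover. `generate_posturelike_channels()`
embeds the scalar slow coordinate into multichannel observations by a
fixed random orthonormal mixing with fast OU channels (time constant
$0.05\,\tau_x$), so the slow mode is linearly recoverable -- a deliberate
idealization: real posture data have curved, nonlinear embeddings, so
passing pipeline tests here demonstrate correctness of the machinery,
not that real postures are linearly encoded. `generate_telegraph()` is
the minimal two-state fixture. Every generator is deterministic given
one master seed (per-realization streams are derived arithmetically) and
carries a manifest sufficient to regenerate it bit-exactly.

## Study problem sizes

The packaged checks run at desk scale, chosen so that each asymptotic
window spans at least a decade while a full run stays within minutes:
frozen-rate ensembles of $10^3$--$10^4$ realizations over windows of
$10^7$--$3\times 10^8\,\tau_x$ for the tail exponents (the paper-scale
analogue uses tens of thousands of realizations); direct-SDE runs of
$10^5$--$3\times 10^5\,\tau_x$ at feasible barriers
($\Delta U/T_x \approx 5$--7) for everything that needs microscopic
dynamics; $10^6$-sample series for estimator-recovery checks. Because
the approach of the fitted exponent to its asymptote is logarithmic in
the window length, fitted tail exponents at any finite scale sit
slightly steep of the formula $-2 - T_x/(2 T_s)$; the residual is about
0.1 with the pure-Pareto MLE and within sampling error for the
log-corrected estimator.

## Known limitations

* The ensemble engines are Kramers-level descriptions: they do not model
  intra-well relaxation or barrier recrossing, and their bulk (short
  dwells near the rate cap) is a caricature; only tails and rate-level
  statistics should be read off them.
* The finite-size correction predicts expectations of covariance
  estimators; normalized-estimator comparisons inherit a small ratio
  bias at short lags.
* Windowed time-dependent inference uses hard overlapping windows; a
  kernel in time would be smoother but is not implemented.
* Scalar reaction coordinates only; no multivariate Langevin inference.
* Trajectory I/O is full-precision delimited text plus JSON manifests;
  for multi-gigabyte ensembles users should regenerate from manifests
  rather than store paths.
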