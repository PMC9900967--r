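#' Residence (first-passage) time container
#'
#' @param durations positive numeric vector of complete dwell times.
#' @param state optional label per duration.
#' @param censored_count number of boundary-truncated intervals excluded.
#' @param min_duration smallest admissible duration (typically the sampling
#'   interval); used for validation only.
#' @param realization optional integer id per duration identifying the
#'   trajectory/realization it came from (used for cluster bootstraps over
#'   ensembles).
#' @return An object of class `residence_times`.
#' @export
residence_times <- function(durations, state = NULL, censored_count = 0L,
                            min_duration = 0, realization = NULL) {
  durations <- as.numeric(durations)
  stopifnot(all(durations >= min_duration), all(durations > 0) || length(durations) == 0)
  if (!is.null(state) && length(state) != length(durations))
    stop("state labels must match durations")
  if (!is.null(realization) && length(realization) != length(durations))
    stop("realization ids must match durations")
  structure(list(durations = durations, state = state,
                 censored_count = as.integer(censored_count),
                 realization = realization),
            class = "residence_times")
}

#' @export
print.residence_times <- function(x, ...) {
  cat("<residence_times>", length(x$durations), "complete dwells,",
      x$censored_count, "censored\n")
  if (length(x$durations))
    cat("  mean =", signif(mean(x$durations), 4),
        " max =", signif(max(x$durations), 4), "\n")
  invisible(x)
}

#' Extract residence times by two-threshold hysteresis
#'
#' Assigns a binary state that switches only when the series crosses the
#' *far* threshold (`x >= upper_thr` for the up state, `x <= lower_thr` for
#' the down state), which suppresses the double counting a single
#' zero-crossing rule produces under fast within-well noise. Durations are
#' the intervals between switches; the first and last intervals are censored
#' by the observation boundaries, excluded from `durations` and counted in
#' `censored_count`.
#'
#' @param traj a [trajectory()] or numeric vector.
#' @param lower_thr,upper_thr hysteresis thresholds, `lower_thr < upper_thr`
#'   (default -0.5 / 0.5 for wells at -1 / +1).
#' @param dt sampling interval when `traj` is a bare numeric vector.
#' @return A [residence_times()] with durations in time units.
#' @export
extract_residence_times <- function(traj, lower_thr = -0.5, upper_thr = 0.5,
                                    dt = NULL) {
  if (inherits(traj, "trajectory")) { x <- traj$x; dt <- traj$dt }
  else { x <- as.numeric(traj); dt <- dt %||% 1 }
  stopifnot(lower_thr < upper_thr, length(x) > 2)
  st <- hysteresis_states(x, lower_thr, upper_thr)
  keep <- !is.na(st)
  if (!any(keep)) return(residence_times(numeric(0), censored_count = 1L))
  r <- rle(st[keep])
  if (length(r$lengths) <= 2) {
    return(residence_times(numeric(0),
                           censored_count = min(length(r$lengths), 2L)))
  }
  mid <- seq(2, length(r$lengths) - 1)
  residence_times(r$lengths[mid] * dt, state = r$values[mid],
                  censored_count = 2L, min_duration = dt)
}

# Vectorized hysteresis state assignment: +1 above upper, -1 below lower,
# last-observation-carried-forward in between (NA before the first crossing).
hysteresis_states <- function(x, lower_thr, upper_thr) {
  st <- rep(NA_real_, length(x))
  st[x >= upper_thr] <- 1
  st[x <= lower_thr] <- -1
  def <- !is.na(st)
  idx <- cumsum(def)
  vals <- st[def]
  out <- rep(NA_real_, length(x))
  out[idx > 0] <- vals[idx[idx > 0]]
  out
}

#' Logarithmically binned probability density
#'
#' Histogram density on geometric bins, normalized so the piecewise-constant
#' integral equals 1. Suited to heavy-tailed positive data.
#'
#' @param durations positive numeric vector with at least 2 distinct values.
#' @param bins_per_decade number of bins per factor of 10 (>= 2).
#' @return A list with `centers` (geometric bin centers), `density`, and
#'   `breaks`.
#' @export
log_binned_pdf <- function(durations, bins_per_decade = 5) {
  durations <- durations[is.finite(durations)]
  stopifnot(all(durations > 0), bins_per_decade >= 2)
  if (length(unique(durations)) < 2)
    stop("degenerate support: need at least two distinct durations")
  lo <- log10(min(durations)); hi <- log10(max(durations))
  nb <- max(2L, ceiling((hi - lo) * bins_per_decade))
  breaks <- 10^seq(lo, hi, length.out = nb + 1)
  breaks[1] <- breaks[1] * (1 - 1e-12)
  breaks[nb + 1] <- breaks[nb + 1] * (1 + 1e-12)
  cnt <- tabulate(findInterval(durations, breaks, rightmost.closed = TRUE),
                  nbins = nb)
  width <- diff(breaks)
  dens <- cnt / (length(durations) * width)
  list(centers = sqrt(breaks[-1] * breaks[-(nb + 1)]), density = dens,
       breaks = breaks)
}

pareto_mle <- function(t, xmin) 1 + length(t) / sum(log(t / xmin))

# MLE for a power law truncated to [xmin, tmax]: solves the score equation
# of f(t) = C t^-alpha with C = (alpha-1)/(xmin^(1-alpha) - tmax^(1-alpha)).
pareto_mle_trunc <- function(t, xmin, tmax) {
  mlog <- mean(log(t / xmin))
  r <- tmax / xmin
  score <- function(alpha) {
    b <- 1 - alpha
    # d/dalpha log C = -1/b ... derived analytically below
    num <- r^b * log(r)
    den <- 1 - r^b
    1 / (alpha - 1) - num / den - mlog
  }
  lo <- 1.01; hi <- 50
  if (score(lo) < 0) return(lo)
  if (score(hi) > 0) return(hi)
  stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
}

pareto_ks <- function(t_sorted, xmin, alpha, tmax = Inf) {
  n <- length(t_sorted)
  b <- 1 - alpha
  Fth <- if (is.finite(tmax)) {
    (1 - (t_sorted / xmin)^b) / (1 - (tmax / xmin)^b)
  } else 1 - (t_sorted / xmin)^b
  Femp_hi <- seq_len(n) / n
  Femp_lo <- (seq_len(n) - 1) / n
  max(abs(Femp_hi - Fth), abs(Femp_lo - Fth))
}

#' Fit a power-law tail by continuous maximum likelihood
#'
#' Continuous Pareto MLE \eqn{\hat\alpha = 1 + n / \sum \ln(t_i/x_{min})},
#' reported as the density exponent `-alpha`. When `xmin` is not given it is
#' chosen by minimizing the Kolmogorov-Smirnov distance between the tail and
#' the fitted power law over a quantile grid of candidates (optionally
#' restricted to `xmin_range`, e.g. an asymptotic window). Confidence
#' intervals come from a nonparametric bootstrap of the full procedure.
#'
#' @param durations positive numeric vector.
#' @param xmin fixed lower cutoff, or `NULL` to select by KS minimization.
#' @param xmin_range optional `c(lo, hi)` restricting candidate cutoffs.
#' @param tmax optional upper cutoff. Durations above it are discarded and
#'   the likelihood of the power law *truncated* to `[xmin, tmax]` is
#'   maximized instead of the plain Pareto likelihood. Use this when the
#'   observation window censors the far tail (dwells comparable to the
#'   record length), where the unbounded MLE is biased steep.
#' @param nboot bootstrap resamples for the 95% CI (default 200).
#' @param n_candidates number of candidate cutoffs scanned.
#' @param boot_max cap on the resample size used during bootstrap (large
#'   samples are subsampled for speed; the CI is then mildly conservative).
#' @param min_tail minimum number of points above the cutoff (default 50).
#' @return An object of class `tail_fit` with fields `exponent`, `xmin`,
#'   `n_tail`, `ci`, `gof` (KS distance at the fit) and `method`.
#' @export
fit_powerlaw_tail <- function(durations, xmin = NULL, xmin_range = NULL,
                              tmax = Inf, nboot = 200, n_candidates = 100,
                              boot_max = 20000, min_tail = 50) {
  t <- as.numeric(durations[is.finite(durations) & durations > 0])
  if (is.finite(tmax)) t <- t[t <= tmax]
  if (!is.null(xmin) && xmin <= 0) stop("xmin must be positive")
  mle <- function(tt, xm) if (is.finite(tmax)) pareto_mle_trunc(tt, xm, tmax)
    else pareto_mle(tt, xm)
  fit1 <- function(t) {
    ts <- sort(t)
    if (is.null(xmin)) {
      cand <- candidate_xmins(ts, xmin_range, n_candidates, min_tail)
      if (!length(cand)) return(NULL)
      best <- NULL; best_ks <- Inf
      for (xm in cand) {
        tt <- ts[ts >= xm]
        a <- mle(tt, xm)
        ks <- pareto_ks(tt, xm, a, tmax)
        if (ks < best_ks) { best_ks <- ks; best <- list(xmin = xm, alpha = a, ks = ks, n = length(tt)) }
      }
      best
    } else {
      tt <- ts[ts >= xmin]
      if (length(tt) < min_tail) return(NULL)
      a <- mle(tt, xmin)
      list(xmin = xmin, alpha = a, ks = pareto_ks(tt, xmin, a, tmax),
           n = length(tt))
    }
  }
  f <- fit1(t)
  if (is.null(f))
    stop("fewer than ", min_tail, " tail points above the cutoff")
  boots <- rep(NA_real_, nboot)
  if (nboot > 0) {
    # resample conditionally on the region the cutoff search lives in, so
    # tail sample sizes are preserved across resamples
    pool_min <- if (!is.null(xmin)) xmin else
      if (!is.null(xmin_range)) xmin_range[1] else min(t)
    pool <- t[t >= pool_min]
    nb <- min(length(pool), boot_max)
    for (b in seq_len(nboot)) {
      fb <- fit1(sample(pool, nb, replace = TRUE))
      if (!is.null(fb)) boots[b] <- -fb$alpha
    }
  }
  expo <- -f$alpha
  ci <- if (any(is.finite(boots)))
    unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE)) else c(NA_real_, NA_real_)
  ci <- c(min(ci[1], expo, na.rm = TRUE), max(ci[2], expo, na.rm = TRUE))
  method <- paste0(if (is.null(xmin)) "mle_ks_xmin" else "mle_fixed_xmin",
                   if (is.finite(tmax)) "_trunc" else "")
  structure(list(exponent = expo, xmin = f$xmin, n_tail = f$n,
                 ci = ci, gof = f$ks, tmax = tmax, method = method),
            class = "tail_fit")
}

candidate_xmins <- function(ts, xmin_range, n_candidates, min_tail) {
  hi_ok <- ts[length(ts) - min_tail + 1]
  lo <- if (is.null(xmin_range)) quantile(ts, 0.01) else xmin_range[1]
  hi <- if (is.null(xmin_range)) hi_ok else min(xmin_range[2], hi_ok)
  if (hi <= lo) return(numeric(0))
  cand <- unique(quantile(ts[ts >= lo & ts <= hi],
                          seq(0, 1, length.out = n_candidates), names = FALSE))
  cand[cand <= hi_ok]
}

#' @export
print.tail_fit <- function(x, ...) {
  cat("<tail_fit> exponent =", round(x$exponent, 3),
      " (95% CI", round(x$ci[1], 3), "to", round(x$ci[2], 3), ")\n")
  cat("  xmin =", signif(x$xmin, 4), " n_tail =", x$n_tail,
      " KS =", round(x$gof, 4), " [", x$method, "]\n")
  invisible(x)
}

#' Tail-exponent MLE for the Kramers-rate mixture with log correction
#'
#' For a Gaussian slow mode mapped through the constant-prefactor Kramers
#' rate `omega = omega0 exp(-deltaU(s)/Tx)`, the induced rate density
#' carries an exact Jacobian factor `1 / sqrt(log(omega0/omega))`, so the
#' dwell-time tail is
#' \deqn{f(t) \propto t^{-\alpha} / \sqrt{\ln(\omega_0 t)},}
#' not a pure power law. Fitting the pure Pareto family to such data biases
#' the exponent steep by about `1/(2 ln(omega0 t))`; this estimator
#' maximizes the likelihood of the corrected family on `[xmin, tmax]`,
#' recovering the asymptotic exponent without that bias. Confidence
#' intervals resample whole realizations when ids are given (dwells from
#' one frozen realization share its rate and are strongly dependent).
#'
#' @param durations positive dwell times, or a [residence_times()].
#' @param omega0 the constant attempt frequency of the rate map.
#' @param xmin,tmax fit window (both required and finite).
#' @param ids optional realization id per duration (taken from a
#'   `residence_times` input automatically); enables the cluster bootstrap.
#' @param nboot bootstrap resamples (default 100).
#' @return A `tail_fit` with `exponent = -alpha_hat`.
#' @export
fit_asymptotic_tail <- function(durations, omega0, xmin, tmax,
                                ids = NULL, nboot = 100) {
  if (inherits(durations, "residence_times")) {
    ids <- ids %||% durations$realization
    durations <- durations$durations
  }
  stopifnot(xmin > 0, is.finite(tmax), tmax > xmin, omega0 * xmin > 1)
  keep <- durations >= xmin & durations <= tmax
  t <- durations[keep]
  if (length(t) < 50) stop("fewer than 50 dwells in the fit window")
  fit1 <- function(tt) {
    nll <- function(alpha) {
      Z <- integrate(function(u) u^(-alpha) / sqrt(log(omega0 * u)),
                     xmin, tmax, rel.tol = 1e-10)$value
      alpha * sum(log(tt)) + 0.5 * sum(log(log(omega0 * tt))) +
        length(tt) * log(Z)
    }
    optimize(nll, c(1.01, 20))$minimum
  }
  alpha <- fit1(t)
  boots <- rep(NA_real_, nboot)
  if (nboot > 0) {
    if (!is.null(ids)) {
      ids <- ids[keep]
      groups <- split(t, ids)
      for (b in seq_len(nboot)) {
        tb <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                     use.names = FALSE)
        if (length(tb) >= 50) boots[b] <- -fit1(tb)
      }
    } else {
      for (b in seq_len(nboot))
        boots[b] <- -fit1(sample(t, replace = TRUE))
    }
  }
  expo <- -alpha
  ci <- if (any(is.finite(boots)))
    unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE)) else c(NA_real_, NA_real_)
  ci <- c(min(ci[1], expo, na.rm = TRUE), max(ci[2], expo, na.rm = TRUE))
  structure(list(exponent = expo, xmin = xmin, n_tail = length(t),
                 ci = ci, gof = NA_real_, tmax = tmax,
                 method = "mle_logcorr_trunc"),
            class = "tail_fit")
}

#' Exponential mixture fit of dwell-time distributions
#'
#' Maximum-likelihood `k`-component exponential mixture by
#' expectation-maximization, the standard description of the *bulk* of
#' metastable dwell-time distributions (each component one effective escape
#' channel). Initialization is deterministic given `seed`.
#'
#' @param durations positive numeric vector, at least 100 points.
#' @param k number of components (1, 2 or 3).
#' @param max_iter,tol EM stopping controls.
#' @param seed seed for the quantile-jittered initialization.
#' @return A list with `rates`, `weights`, `loglik`, `n_iter`, `converged`.
#' @export
fit_exponential_mixture <- function(durations, k, max_iter = 500, tol = 1e-8,
                                    seed = 1L) {
  t <- as.numeric(durations)
  stopifnot(k %in% 1:3, length(t) >= 100, all(t > 0))
  set.seed(seed)
  qs <- quantile(t, probs = (seq_len(k) - 0.5) / k)
  lam <- 1 / (qs * runif(k, 0.9, 1.1))
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- sapply(seq_len(k), function(j) log(w[j]) + log(lam[j]) - lam[j] * t)
    if (k == 1) logd <- matrix(logd, ncol = 1)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    r <- exp(logd - lse)
    w <- colMeans(r)
    lam <- colSums(r) / colSums(r * t)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      o <- order(lam)
      return(list(rates = unname(lam[o]), weights = unname(w[o]),
                  loglik = ll, n_iter = it, converged = TRUE))
    }
    ll_old <- ll
  }
  stop("EM did not converge in ", max_iter,
       " iterations (last log-likelihood ", signif(ll_old, 8), ")")
}

#' Distribution of escape rates
#'
#' Container for the density `p(omega)` of hopping rates induced by the
#' slow-mode fluctuations (or supplied directly). The density is normalized
#' at construction over `[omega_min, omega_max]`. A point mass is encoded by
#' `omega_min == omega_max`.
#'
#' @param density function of omega (unnormalized is fine), or `NULL` for a
#'   point mass at `omega_min`.
#' @param omega_min,omega_max support bounds (positive).
#' @param provenance free-text origin tag.
#' @return An object of class `rate_distribution`.
#' @export
rate_distribution <- function(density = NULL, omega_min, omega_max,
                              provenance = "user") {
  stopifnot(omega_min > 0, omega_max >= omega_min)
  if (omega_min == omega_max) {
    return(structure(list(density = NULL, omega_min = omega_min,
                          omega_max = omega_max, point_mass = TRUE,
                          provenance = provenance),
                     class = "rate_distribution"))
  }
  Z <- rate_quad(density, omega_min, omega_max)
  if (!is.finite(Z) || Z <= 0)
    stop("density must be non-negative with positive mass")
  dens <- function(w) density(w) / Z
  chk <- rate_quad(dens, omega_min, omega_max)
  if (abs(chk - 1) > 1e-6) stop("density failed to normalize to 1 within 1e-6")
  structure(list(density = dens, omega_min = omega_min,
                 omega_max = omega_max, point_mass = FALSE,
                 provenance = provenance),
            class = "rate_distribution")
}

#' Rate distribution induced by Boltzmann slow-mode statistics
#'
#' Maps the Boltzmann weight `exp(-V(s)/Ts)` of the frozen slow mode through
#' the Kramers rate `omega(s)` to obtain a tabulated density `p(omega)` on a
#' logarithmic grid (summing both branches of the non-monotone map).
#'
#' @inheritParams kramers_rate
#' @param Ts slow noise level (> 0).
#' @param omega_range optional `c(min, max)` truncation of the support;
#'   default spans the rates reached on `mu_s +/- 8 sd`.
#' @param n_grid resolution of the slow-mode grid.
#' @return A [rate_distribution()].
#' @export
induced_rate_distribution <- function(potential, Tx, Ts, omega0 = NULL,
                                      omega_range = NULL, n_grid = 2e5) {
  mu <- potential$mu_s
  half <- 8 * sqrt(Ts) + abs(mu)
  sg <- seq(mu - half, mu + half, length.out = n_grid)
  sg <- sg[potential$deltaU(sg) > 0]
  w <- kramers_rate(sg, potential, Tx, omega0)
  p_s <- exp(-(potential$V(sg) - min(potential$V(sg))) / Ts)
  rng <- omega_range %||% range(w)
  keep <- w >= rng[1] & w <= rng[2]
  w <- w[keep]; p_s <- p_s[keep]
  nb <- 400L
  lb <- seq(log(rng[1]) - 1e-9, log(rng[2]) + 1e-9, length.out = nb + 1)
  bin <- findInterval(log(w), lb, rightmost.closed = TRUE)
  mass <- vapply(seq_len(nb), function(b) sum(p_s[bin == b]), numeric(1))
  width <- exp(lb[-1]) - exp(lb[-(nb + 1)])
  dens_tab <- mass / width
  centers <- exp((lb[-1] + lb[-(nb + 1)]) / 2)
  dfun <- approxfun(centers, dens_tab, rule = 2)
  rate_distribution(dfun, rng[1], rng[2], provenance = "boltzmann_kramers")
}

#' First-passage-time mixture density
#'
#' Numerical quadrature of the rate-mixture FPTD
#' \deqn{f(t) \propto \int p(\omega)\, \omega \cdot \omega e^{-\omega t}\, d\omega,}
#' where one factor of omega weights each rate by its number of transitions
#' within the observation window and \eqn{\omega e^{-\omega t}} is the
#' static-well escape density. When `normalize = TRUE` the result is
#' normalized analytically over `[min(t_grid), Inf)` using
#' \eqn{\int_{t_0}^\infty \omega^2 e^{-\omega t} dt = \omega e^{-\omega t_0}}.
#'
#' @param rates a [rate_distribution()].
#' @param t_grid positive ascending evaluation times.
#' @param normalize logical.
#' @return Density values on `t_grid`.
#' @export
fptd_mixture <- function(rates, t_grid, normalize = TRUE) {
  stopifnot(inherits(rates, "rate_distribution"),
            all(t_grid > 0), !is.unsorted(t_grid))
  if (rates$point_mass) {
    w <- rates$omega_min
    f <- w^2 * exp(-w * t_grid)
    if (normalize) f <- f / (w * exp(-w * t_grid[1]))
    return(f)
  }
  f <- vapply(t_grid, function(t)
    rate_quad(function(w) rates$density(w) * w^2 * exp(-w * t),
              rates$omega_min, rates$omega_max), numeric(1))
  if (normalize) {
    t0 <- t_grid[1]
    Z <- rate_quad(function(w) rates$density(w) * w * exp(-w * t0),
                   rates$omega_min, rates$omega_max)
    f <- f / Z
  }
  f
}

# Quadrature over a rate support spanning many decades. Integrates in
# log(omega), where exponentially localized integrands are wide, with a
# log-grid trapezoid fallback; errors only if both routes fail.
rate_quad <- function(g, wmin, wmax) {
  if (wmax / wmin < 10) {
    r <- tryCatch(integrate(g, wmin, wmax, rel.tol = 1e-9,
                            subdivisions = 2000L, stop.on.error = FALSE),
                  error = function(e) list(message = "failed"))
    if (identical(r$message, "OK")) return(r$value)
  } else {
    r <- tryCatch(integrate(function(v) g(exp(v)) * exp(v),
                            log(wmin), log(wmax), rel.tol = 1e-9,
                            subdivisions = 2000L, stop.on.error = FALSE),
                  error = function(e) list(message = "failed"))
    if (identical(r$message, "OK")) return(r$value)
  }
  wg <- exp(seq(log(wmin), log(wmax), length.out = 2e5))
  gv <- g(wg)
  v <- sum(diff(wg) * (head(gv, -1) + tail(gv, -1)) / 2)
  if (!is.finite(v)) stop("quadrature failed over [", wmin, ", ", wmax, "]")
  v
}

#' Asymptotic first-passage-time density shape
#'
#' Dominant-order large-`t` asymptotics of the rate-mixture FPTD for
#' Boltzmann-distributed slow modes:
#' \deqn{f(t) \sim t^{-2} \exp\left[-V(\Delta U^{-1}(T_x \ln \omega_0 t)) / T_s\right].}
#' With `Ts = Inf` this is exactly the `t^-2` shape; for `V` and `deltaU`
#' asymptotically equivalent it is a power law `t^(-2 - c Tx/Ts)`.
#'
#' @inheritParams kramers_rate
#' @param Ts slow noise level, may be `Inf`.
#' @param omega0 constant attempt frequency setting the time scale.
#' @param t_grid evaluation times with `t_grid * omega0 > 1`.
#' @return Unnormalized density shape on `t_grid`.
#' @export
asymptotic_fptd <- function(potential, Tx, Ts, omega0, t_grid) {
  stopifnot(all(t_grid * omega0 > 1))
  y <- Tx * log(omega0 * t_grid)
  s_of_t <- potential$deltaU_inv(y)
  if (any(!is.finite(s_of_t)))
    stop("deltaU_inv undefined for the requested argument range")
  expo <- if (is.infinite(Ts)) rep(0, length(t_grid)) else
    -potential$V(s_of_t) / Ts
  t_grid^(-2) * exp(expo)
}

#' Asymptotic power-law tail exponent
#'
#' The predicted FPTD tail exponent `-2 - c * Tx / Ts` for asymptotically
#' equivalent `V` and `deltaU` (with `c = 1/2` for the default quartic
#' double well where `V(deltaU_inv(y)) ~ y/2`), reducing to the universal
#' `-2` when `Ts` is infinite or `Tx` is 0.
#'
#' @param Tx fast noise level.
#' @param Ts slow noise level (> 0 or `Inf`).
#' @param c potential-shape constant (default 1/2).
#' @return The exponent (a negative number).
#' @export
asymptotic_exponent <- function(Tx, Ts, c = 0.5) {
  stopifnot(c > 0)
  if (any(Ts <= 0)) stop("Ts must be positive (possibly infinite)")
  ifelse(is.infinite(Ts) | Tx == 0, -2, -2 - c * Tx / Ts)
}
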