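#' Correlation estimate container
#'
#' @param lags non-negative ascending lag values (time units).
#' @param values correlation values at those lags.
#' @param estimator one of `"connected_timeavg"`, `"nonconnected_ensemble"`,
#'   `"model"`, `"finite_size_corrected"`.
#' @param n_series number of series averaged.
#' @param T_obs observation duration per series.
#' @param mu_hat,var_hat sample mean/variance used (connected estimator).
#' @return An object of class `correlation_estimate`.
#' @export
correlation_estimate <- function(lags, values, estimator, n_series = 1L,
                                 T_obs = NA_real_, mu_hat = NA_real_,
                                 var_hat = NA_real_) {
  stopifnot(length(lags) == length(values), all(lags >= 0), !is.unsorted(lags))
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 estimator = estimator, n_series = as.integer(n_series),
                 T_obs = T_obs, mu_hat = mu_hat, var_hat = var_hat),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat("<correlation_estimate>", x$estimator, "-", length(x$lags), "lags,",
      x$n_series, "series, T_obs =", x$T_obs, "\n")
  invisible(x)
}

resolve_lag_samples <- function(lags, dt, max_lag, n) {
  if (is.null(lags)) {
    L <- seq(0L, floor(max_lag / dt))
  } else {
    stopifnot(all(lags >= 0))
    L <- sort(unique(as.integer(round(lags / dt))))
  }
  L[L < n]
}

#' Connected autocorrelation by temporal averaging
#'
#' The per-series sample mean is subtracted and the autocovariance is
#' normalized by the per-series sample variance, then estimates are averaged
#' with equal weight across series. This is the estimator a single finite
#' recording permits; when slow time scales are comparable to the record
#' length, the sample-mean subtraction biases it negative at large lags (see
#' [finite_size_correction()]).
#'
#' @param series numeric vector or list of numeric vectors.
#' @param dt sampling interval.
#' @param max_lag largest lag (time units); each series must be at least
#'   twice this long.
#' @param lags optional explicit lag grid (time units); defaults to every
#'   multiple of `dt` up to `max_lag`.
#' @param normalize_variance divide each series' autocovariance by its
#'   sample variance (default), so the estimate is 1 at lag 0; with
#'   `FALSE` the raw mean-subtracted autocovariance is averaged instead
#'   (the scale on which the finite-size correction is exact).
#' @return A [correlation_estimate()] (value 1 at lag 0 when normalized).
#' @export
connected_acf_timeavg <- function(series, dt, max_lag, lags = NULL,
                                  normalize_variance = TRUE) {
  if (!is.list(series)) series <- list(series)
  n <- length(series[[1]])
  stopifnot(n >= 2 * max_lag / dt)
  L <- resolve_lag_samples(lags, dt, max_lag, n)
  if (L[1] != 0L) L <- c(0L, L)
  acc <- 0
  mus <- vars <- numeric(length(series))
  for (i in seq_along(series)) {
    x <- as.numeric(series[[i]])
    v <- cpp_acf_lags(x, L, TRUE)
    if (!is.finite(v[1]) || v[1] <= 0)
      stop("series has zero variance; connected ACF undefined")
    mus[i] <- mean(x); vars[i] <- v[1]
    acc <- acc + if (normalize_variance) v / v[1] else v
  }
  correlation_estimate(L * dt, acc / length(series), "connected_timeavg",
                       n_series = length(series), T_obs = (n - 1) * dt,
                       mu_hat = mean(mus), var_hat = mean(vars))
}

#' Non-connected autocorrelation over an ensemble
#'
#' Ensemble estimator `<x(t) x(t+tau)>` without mean subtraction, averaged
#' across trajectories and start times. For a symmetric landscape the
#' ensemble mean vanishes, so this estimator accesses the true correlation
#' tail free of the sample-mean bias. By convention the curve is normalized
#' by its value at the first reported positive lag (set
#' `normalize = "none"` for raw values).
#'
#' @param trajectories list of [trajectory()] objects or numeric vectors.
#' @param dt sampling interval (taken from the trajectories when available;
#'   all must agree).
#' @param max_lag largest lag in time units.
#' @param lags optional explicit lag grid (time units).
#' @param normalize `"first_lag"` (default) or `"none"`.
#' @return A [correlation_estimate()].
#' @export
nonconnected_acf_ensemble <- function(trajectories, dt = NULL, max_lag,
                                      lags = NULL,
                                      normalize = c("first_lag", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(trajectories) >= 2)
  xs <- lapply(trajectories, function(tr)
    if (inherits(tr, "trajectory")) tr$x else as.numeric(tr))
  dts <- vapply(trajectories, function(tr)
    if (inherits(tr, "trajectory")) tr$dt else NA_real_, numeric(1))
  dts <- dts[!is.na(dts)]
  if (length(dts)) {
    if (max(abs(dts - dts[1])) > 1e-12 * dts[1])
      stop("trajectories have unequal sampling intervals")
    dt <- dts[1]
  }
  if (is.null(dt)) stop("dt must be supplied for bare numeric series")
  n <- min(lengths(xs))
  L <- resolve_lag_samples(lags, dt, max_lag, n)
  acc <- 0
  for (x in xs) acc <- acc + cpp_acf_lags(x[seq_len(n)], L, FALSE)
  vals <- acc / length(xs)
  if (normalize == "first_lag") {
    Lpos <- which(L > 0)
    if (!length(Lpos)) stop("no positive lag to normalize at")
    vals <- vals / vals[Lpos[1]]
  }
  correlation_estimate(L * dt, vals, "nonconnected_ensemble",
                       n_series = length(xs), T_obs = (n - 1) * dt)
}

#' Correlation function of a rate mixture
#'
#' Quadrature of \eqn{C(\tau) = \int p(\omega) e^{-\omega\tau} d\omega}: the
#' correlation analogue of the FPTD mixture, in which the integrand carries
#' no transition-count weighting and no escape-density prefactor (it is the
#' FPTD integrand divided by \eqn{\omega^2}).
#'
#' @param rates a [rate_distribution()].
#' @param tau_grid positive ascending lags.
#' @return Correlation values (equal to 1 at `tau = 0` by normalization of
#'   `p`).
#' @export
mixture_correlation <- function(rates, tau_grid) {
  stopifnot(inherits(rates, "rate_distribution"),
            all(tau_grid >= 0), !is.unsorted(tau_grid))
  if (rates$point_mass) return(exp(-rates$omega_min * tau_grid))
  vapply(tau_grid, function(tau)
    rate_quad(function(w) rates$density(w) * exp(-w * tau),
              rates$omega_min, rates$omega_max), numeric(1))
}

#' Asymptotic correlation tail shape
#'
#' Dominant-order large-lag behavior of the slowly modulated correlation
#' function,
#' \deqn{C_x(\tau) \sim \exp[-V(\Delta U^{-1}(T_x \ln \omega_0 \tau)) / T_s],}
#' i.e. the FPTD asymptotics without the `t^-2` factor, so the tail
#' exponents obey `gamma = beta + 2`. Constant (slope 0) when `Ts = Inf`;
#' slope `-Tx/(2 Ts)` for the default quartic double well.
#'
#' @inheritParams asymptotic_fptd
#' @param tau_grid lags with `tau_grid * omega0 > 1`.
#' @return Unnormalized shape on `tau_grid`.
#' @export
asymptotic_correlation <- function(potential, Tx, Ts, omega0, tau_grid) {
  asymptotic_fptd(potential, Tx, Ts, omega0, tau_grid) * tau_grid^2
}

#' Finite-size correction of the time-averaged connected estimator
#'
#' For a stationary process observed over a finite window `T_obs`, the
#' sample mean deviates from the ensemble mean, which biases the
#' mean-subtracted (connected) autocovariance estimator negative at large
#' lags. Writing `m(t) = Cov(x_t, mu_hat) = (1/T) int_0^T C(|t-u|) du` and
#' \deqn{\mathrm{Var}(\hat\mu) = \frac{2}{T} \int_0^{T} (1 - u/T)\, C(u)\, du,}
#' the expectation of the estimator is, exactly at second order,
#' \deqn{E[\hat C(\tau)] = C(\tau) - \mathrm{avg}_t\,[m(t) + m(t+\tau)] +
#'   \mathrm{Var}(\hat\mu),}
#' with the average over admissible start times (`method = "exact"`,
#' validated against ensemble Monte Carlo). `method = "mean_variance"`
#' keeps only the lag-independent leading term `C(tau) - Var(mu_hat)`. Slow
#' components inflate `Var(mu_hat)`, so corrected curves cross zero: the
#' apparent long-range anti-correlations of finite recordings.
#'
#' The exact method predicts the expected *autocovariance*; the empirical
#' estimator normalized by the sample variance carries an additional small
#' ratio bias not modeled here, so comparisons are best made at the
#' covariance level (see [connected_acf_timeavg()]'s `var_hat` field).
#'
#' @param correlation_model a [correlation_estimate()] (or list with
#'   `lags`, `values`) giving the true normalized correlation on a uniform
#'   lag grid starting at 0 and covering `[0, T_obs]`.
#' @param T_obs observation duration of the estimator being corrected; must
#'   not exceed the largest model lag.
#' @param method `"exact"` (default) or `"mean_variance"`.
#' @param normalize if `TRUE`, rescale the corrected curve by its value at
#'   lag 0 (approximating the variance-normalized estimator).
#' @return A [correlation_estimate()] with estimator
#'   `"finite_size_corrected"` on the lags up to `T_obs`; values may be
#'   negative. The field `mean_variance` holds `Var(mu_hat)`.
#' @export
finite_size_correction <- function(correlation_model, T_obs,
                                   method = c("exact", "mean_variance"),
                                   normalize = FALSE) {
  method <- match.arg(method)
  lags <- correlation_model$lags
  vals <- correlation_model$values
  stopifnot(length(lags) == length(vals), T_obs > 0)
  if (max(lags) < T_obs)
    stop("correlation model must cover lags up to T_obs (T_obs <= max lag ",
         "is required)")
  inside <- lags <= T_obs + 1e-9
  u <- lags[inside]; cu <- vals[inside]
  du <- diff(u)
  if (u[1] != 0 || max(abs(du - du[1])) > 1e-6 * du[1])
    stop("the model must be tabulated on a uniform lag grid starting at 0")
  dt <- du[1]; n <- length(u)
  cumC <- c(0, cumsum((head(cu, -1) + tail(cu, -1)) / 2 * dt))
  m <- (cumC[seq_len(n)] + cumC[n:1]) / T_obs
  V <- sum((head(m, -1) + tail(m, -1)) / 2 * dt) / T_obs
  corrected <- if (method == "exact") {
    vapply(seq_len(n), function(k) {
      idx <- seq_len(n - k + 1)
      cu[k] - mean(m[idx] + m[idx + k - 1]) + V
    }, numeric(1))
  } else {
    cu - V
  }
  if (normalize) corrected <- corrected / corrected[1]
  out <- correlation_estimate(u, corrected, "finite_size_corrected",
                              n_series = 1L, T_obs = T_obs)
  out$mean_variance <- V
  out$method <- method
  out
}

#' Log-log slope of a correlation or density tail
#'
#' Least-squares slope of `log(value)` against `log(lag)` over a window,
#' the simple regression estimate of a power-law exponent used for
#' correlation tails (where the MLE machinery of densities does not apply).
#'
#' @param lags,values the curve; only strictly positive entries enter.
#' @param window `c(lo, hi)` restricting the lags used.
#' @return A list with `slope`, `se` (regression standard error), and `n`.
#' @export
fit_loglog_slope <- function(lags, values, window = range(lags[lags > 0])) {
  keep <- lags >= window[1] & lags <= window[2] & values > 0 & lags > 0
  if (sum(keep) < 3) stop("need at least 3 positive points in the window")
  lx <- log(lags[keep]); ly <- log(values[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  se <- tryCatch({
    r <- fit$residuals
    sqrt(sum(r^2) / (length(ly) - 2) / sum((lx - mean(lx))^2))
  }, error = function(e) NA_real_)
  list(slope = unname(fit$coefficients[2]), se = se, n = sum(keep))
}
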