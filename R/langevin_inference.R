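#' Kramers-Moyal drift/diffusion model container
#'
#' @param grid strictly ascending coordinate grid.
#' @param F,D drift and diffusion values on the grid (`NA` where masked).
#' @param bandwidth kernel bandwidth used.
#' @param tau_star sampling interval of the increments.
#' @param support_counts data points supporting each grid value.
#' @param min_count occupancy below which values are masked.
#' @return An object of class `km_model`.
#' @export
km_model <- function(grid, F, D, bandwidth, tau_star, support_counts,
                     min_count = 20L) {
  stopifnot(!is.unsorted(grid, strictly = TRUE),
            length(F) == length(grid), length(D) == length(grid))
  mask <- support_counts < min_count
  F[mask] <- NA_real_; D[mask] <- NA_real_
  if (any(D < 0, na.rm = TRUE)) D[which(D < 0)] <- 0
  structure(list(grid = grid, F = F, D = D, bandwidth = bandwidth,
                 tau_star = tau_star, support_counts = support_counts,
                 min_count = as.integer(min_count)),
            class = "km_model")
}

#' @export
print.km_model <- function(x, ...) {
  cat("<km_model>", length(x$grid), "grid points on [",
      signif(min(x$grid), 3), ",", signif(max(x$grid), 3), "], tau* =",
      x$tau_star, ", h =", signif(x$bandwidth, 3), "\n")
  cat("  masked:", sum(is.na(x$F)), "points below occupancy",
      x$min_count, "\n")
  invisible(x)
}

silverman_bw <- function(x) 1.06 * sd(x) * length(x)^(-1/5)

#' Estimate drift and diffusion by kernel Kramers-Moyal regression
#'
#' Local-linear kernel regression (Epanechnikov weights) of the first two
#' conditional moments of the increment over `tau_star`:
#' \deqn{\hat F(x) = E[\Delta x \mid x] / \tau^*, \qquad
#'       \hat D(x) = E[(\Delta x - \hat F \tau^*)^2 \mid x] / (2\tau^*),}
#' where the conditional mean is the intercept of a weighted linear fit at
#' each grid point (local-linear fits cancel the density-gradient bias a
#' local-constant smoother has) and the diffusion estimator uses the
#' residual variance about that fit, subtracting the drift contribution at
#' first order. Grid points whose kernel neighborhood holds fewer than
#' `min_count` samples are masked (`NA`), never extrapolated.
#'
#' @param series scalar time series (e.g. a slow reaction coordinate).
#' @param dt sampling interval of `series`.
#' @param tau_star increment interval; must be a multiple of `dt`. Choose it
#'   with [select_markov_einstein_time()] so increments are effectively
#'   white.
#' @param bandwidth Epanechnikov half-width; default Silverman-type rule on
#'   the series scale.
#' @param grid evaluation grid; default 51 points spanning the central
#'   99.8% of the data.
#' @param min_count minimal kernel occupancy per reported grid point.
#' @return A [km_model()].
#' @export
estimate_drift_diffusion <- function(series, dt, tau_star, bandwidth = NULL,
                                     grid = NULL, min_count = 20L) {
  x <- as.numeric(series)
  step <- tau_star / dt
  if (abs(step - round(step)) > 1e-8) stop("tau_star must be a multiple of dt")
  step <- as.integer(round(step))
  stopifnot(step >= 1, length(x) > step + 1, !is.null(bandwidth) || sd(x) > 0)
  X <- x[seq_len(length(x) - step)]
  DX <- x[-seq_len(step)] - X
  h <- bandwidth %||% silverman_bw(X)
  stopifnot(h > 0)
  if (is.null(grid)) {
    qs <- quantile(X, c(0.001, 0.999), names = FALSE)
    grid <- seq(qs[1], qs[2], length.out = 51)
  }
  mom <- cpp_nw_moments(X, DX, grid, h)
  det <- mom$Sw * mom$Sxx - mom$Sx^2
  ok <- mom$Sw > 0 & det > .Machine$double.eps * pmax(mom$Sw, 1)^2
  a <- ifelse(ok, (mom$Sxx * mom$Sy - mom$Sx * mom$Sxy) / det, NA_real_)
  b <- ifelse(ok, (mom$Sw * mom$Sxy - mom$Sx * mom$Sy) / det, NA_real_)
  Fh <- a / tau_star
  rss <- mom$Syy - 2 * a * mom$Sy - 2 * b * mom$Sxy + a^2 * mom$Sw +
    2 * a * b * mom$Sx + b^2 * mom$Sxx
  Dh <- ifelse(ok, rss / mom$Sw, NA_real_) / (2 * tau_star)
  km_model(grid, Fh, Dh, h, tau_star, mom$count, min_count)
}

#' Interpolate an inferred drift or diffusion function
#'
#' Linear interpolation of a [km_model()]'s `F` or `D` over the unmasked
#' grid (constant extrapolation at the edges).
#'
#' @param model a [km_model()].
#' @param x coordinates to evaluate at.
#' @param what `"F"` or `"D"`.
#' @return Numeric values at `x`.
#' @export
km_interp <- function(model, x, what = c("F", "D")) {
  what <- match.arg(what)
  ok <- !is.na(model[[what]])
  approx(model$grid[ok], model[[what]][ok], xout = x, rule = 2)$y
}

#' Choose the Markov-Einstein sampling interval
#'
#' For each candidate lag a provisional Kramers-Moyal model is fitted and
#' the standardized residual noise of non-overlapping increments,
#' \eqn{\eta_i = (\Delta x_i - \hat F \tau)/\sqrt{2 \hat D \tau}}, is
#' formed. The smallest lag whose residual lag-1 autocorrelation magnitude
#' falls below `threshold` is returned; an overdamped Langevin description
#' sampled at that interval has effectively delta-correlated fluctuations.
#' If no candidate qualifies the largest is returned with a warning and
#' `qualified = FALSE`.
#'
#' @param series,dt scalar series and its sampling interval.
#' @param candidate_lags ascending multiples of `dt` (time units).
#' @param threshold residual autocorrelation magnitude to accept (default
#'   0.05).
#' @return List with `tau_star`, `qualified`, and the per-candidate residual
#'   autocorrelations `r1`.
#' @export
select_markov_einstein_time <- function(series, dt, candidate_lags,
                                        threshold = 0.05) {
  stopifnot(!is.unsorted(candidate_lags), all(candidate_lags > 0))
  x <- as.numeric(series)
  if (length(x) < 100 * max(candidate_lags) / dt)
    stop("series is shorter than 100x the largest candidate lag")
  r1 <- vapply(candidate_lags, function(tau) {
    step <- as.integer(round(tau / dt))
    m <- estimate_drift_diffusion(x, dt, step * dt)
    idx <- seq(1L, length(x) - step, by = step)
    eta <- (x[idx + step] - x[idx] - km_interp(m, x[idx], "F") * tau) /
      sqrt(pmax(2 * km_interp(m, x[idx], "D") * tau, .Machine$double.eps))
    cor(eta[-length(eta)], eta[-1])
  }, numeric(1))
  ok <- which(abs(r1) < threshold)
  if (length(ok)) {
    list(tau_star = candidate_lags[ok[1]], qualified = TRUE, r1 = r1)
  } else {
    warning("no candidate lag gave residual autocorrelation below ",
            threshold, "; returning the largest candidate")
    list(tau_star = candidate_lags[length(candidate_lags)],
         qualified = FALSE, r1 = r1)
  }
}

#' Time-dependent Kramers-Moyal inference on overlapping windows
#'
#' Splits the series into overlapping windows that tile the observation
#' span (the final window is anchored at the end) and applies
#' [estimate_drift_diffusion()] per window on a common grid, yielding
#' drift and diffusion surfaces `F(x, t)`, `D(x, t)` evaluated at window
#' midpoints.
#'
#' @inheritParams estimate_drift_diffusion
#' @param bandwidth_x per-window kernel bandwidth (default Silverman on the
#'   full series).
#' @param window_len window length in time units (>= `100 * tau_star`).
#' @param overlap fractional overlap between consecutive windows (default
#'   0.5).
#' @return An object of class `tv_km_model`: window `centers`, list of
#'   per-window [km_model()]s, and the shared grid.
#' @export
estimate_time_dependent <- function(series, dt, tau_star, bandwidth_x = NULL,
                                    window_len, overlap = 0.5, grid = NULL,
                                    min_count = 20L) {
  x <- as.numeric(series)
  stopifnot(window_len >= 100 * tau_star, overlap >= 0, overlap < 1)
  wlen <- as.integer(round(window_len / dt))
  stride <- max(1L, as.integer(round(wlen * (1 - overlap))))
  starts <- seq(1L, length(x) - wlen + 1L, by = stride)
  if (starts[length(starts)] + wlen - 1L < length(x))
    starts <- c(starts, length(x) - wlen + 1L)
  if (length(starts) < 2)
    stop("fewer than 2 windows; use the stationary estimator instead")
  h <- bandwidth_x %||% silverman_bw(x)
  if (is.null(grid)) {
    qs <- quantile(x, c(0.001, 0.999), names = FALSE)
    grid <- seq(qs[1], qs[2], length.out = 51)
  }
  models <- lapply(starts, function(s0)
    estimate_drift_diffusion(x[s0:(s0 + wlen - 1L)], dt, tau_star,
                             bandwidth = h, grid = grid,
                             min_count = min_count))
  centers <- (starts - 1 + (wlen - 1) / 2) * dt
  structure(list(centers = centers, models = models, grid = grid,
                 window_len = wlen * dt, overlap = overlap,
                 tau_star = tau_star, bandwidth = h,
                 T_total = (length(x) - 1) * dt),
            class = "tv_km_model")
}

#' @export
print.tv_km_model <- function(x, ...) {
  cat("<tv_km_model>", length(x$models), "windows of length", x$window_len,
      "(overlap", x$overlap, ") on", length(x$grid), "grid points\n")
  invisible(x)
}

#' Effective potential from an inferred drift
#'
#' Integrates `U(x) = -int F dx` by cumulative trapezoid over the
#' contiguous unmasked grid segment and shifts the minimum to zero. Masked
#' interior points are an error: gaps are never interpolated across.
#'
#' @param model a [km_model()].
#' @return List with `grid` and `U` over the unmasked segment.
#' @export
potential_from_drift <- function(model) {
  ok <- which(!is.na(model$F))
  if (!length(ok)) stop("no unmasked grid points")
  if (!identical(ok, seq(min(ok), max(ok))))
    stop("masked interior grid point: drift support is not contiguous")
  g <- model$grid[ok]; f <- model$F[ok]
  U <- c(0, cumsum(diff(g) * (head(f, -1) + tail(f, -1)) / 2)) * -1
  list(grid = g, U = U - min(U))
}

#' Simulate an inferred Kramers-Moyal model
#'
#' Euler-Maruyama simulation with linear interpolation of the inferred
#' drift and diffusion in `x` (piecewise-constant in time across windows
#' for a time-varying model) and reflecting behavior at the grid edges,
#' since the inferred coefficients are unreliable outside the sampled
#' range. More than 1% of steps beyond the grid aborts with advice to
#' widen it.
#'
#' @param model a [km_model()] or `tv_km_model`.
#' @param duration simulated duration; 0 gives an empty trajectory.
#' @param seed RNG seed.
#' @param dt integration step (default `tau_star / 10`).
#' @param x0 initial value (default: highest-occupancy grid point).
#' @param keep_every thinning of the stored path.
#' @return A [trajectory()].
#' @export
simulate_km_model <- function(model, duration, seed = 1L,
                              dt = NULL, x0 = NULL, keep_every = 1L) {
  tv <- inherits(model, "tv_km_model")
  mods <- if (tv) model$models else list(model)
  dt <- dt %||% (model$tau_star / 10)
  if (duration <= 0) return(trajectory(numeric(0), dt))
  ok <- Reduce(`&`, lapply(mods, function(m) !is.na(m$F) & !is.na(m$D)))
  seg <- longest_true_run(ok)
  if (length(seg) < 2) stop("no contiguous unmasked grid segment shared by all windows")
  grid <- mods[[1]]$grid[seg]
  Fm <- sapply(mods, function(m) m$F[seg])
  Dm <- sapply(mods, function(m) m$D[seg])
  if (min(Dm) <= 0) stop("D must be positive on the simulated support")
  n_steps <- floor(duration / dt)
  win_id <- if (tv) {
    tgrid <- (seq_len(n_steps) - 1) * dt
    scaled <- tgrid / duration * model$T_total
    as.integer(vapply(scaled, function(t) which.min(abs(model$centers - t)) - 1L,
                      integer(1)))
  } else 0L
  if (is.null(x0)) {
    cnt <- mods[[1]]$support_counts[seg]
    x0 <- grid[which.max(cnt)]
  }
  set.seed(seed)
  res <- cpp_sim_km(grid, as.matrix(Fm), as.matrix(Dm), win_id,
                    n_steps, dt, x0, as.integer(keep_every))
  if (res$n_out / max(n_steps, 1) > 0.01)
    stop("more than 1% of steps left the grid; refit on a wider grid")
  trajectory(res$x, dt * keep_every)
}

longest_true_run <- function(ok) {
  r <- rle(ok)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  seq(starts[i], ends[i])
}
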