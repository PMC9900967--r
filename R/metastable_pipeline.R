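#' Delay embedding of multichannel series
#'
#' Stacks `K` consecutive frames into each row so that short-term history
#' becomes part of the state, restoring an approximately Markovian
#' description of partially observed dynamics. Row `t` holds frames
#' `t, ..., t + K - 1` with the most recent frame last.
#'
#' @param channels numeric vector or matrix (rows: time, columns: channels).
#' @param K embedding depth (>= 1); `K = 1` is an identity reshape.
#' @return An object of class `embedded_series`: a matrix with
#'   `nrow = length - K + 1` rows and `K * n_channels` columns, with
#'   attributes `K` and `n_channels`.
#' @export
delay_embed <- function(channels, K) {
  m <- if (is.matrix(channels)) channels else matrix(channels, ncol = 1)
  n <- nrow(m); nc <- ncol(m)
  stopifnot(K >= 1)
  if (K >= n + 1) stop("K must be smaller than the series length")
  rows <- n - K + 1
  out <- matrix(NA_real_, rows, K * nc)
  for (j in seq_len(K)) out[, ((j - 1) * nc + 1):(j * nc)] <- m[j:(j + rows - 1), , drop = FALSE]
  structure(out, K = K, n_channels = nc, class = c("embedded_series", "matrix", "array"))
}

#' Cluster delay-embedded frames into microstates
#'
#' k-means partition of the embedded state space (fixed seed, 10 restarts)
#' into discrete microstates whose transition statistics discretize the
#' transfer operator.
#'
#' @param embedded an [delay_embed()] matrix (or any numeric matrix).
#' @param n_states number of microstates (>= 2, at most `nrow / 10`).
#' @param seed RNG seed.
#' @return List with integer `labels` (1-based, length `nrow`) and the
#'   `centers` matrix.
#' @export
cluster_microstates <- function(embedded, n_states, seed = 1L) {
  m <- unclass(embedded)
  attr(m, "K") <- NULL; attr(m, "n_channels") <- NULL
  stopifnot(n_states >= 2, n_states <= nrow(m) / 10)
  if (all(apply(m, 2, function(col) diff(range(col)) == 0)))
    stop("degenerate input: all embedded rows identical")
  set.seed(seed)
  km <- kmeans(m, centers = n_states, nstart = 10, iter.max = 100)
  list(labels = as.integer(km$cluster), centers = km$centers)
}

#' Row-stochastic transition matrix of a label sequence
#'
#' Counts label pairs at distance `lag` and row-normalizes. States with no
#' outgoing transitions at that lag receive a self-loop row so the matrix
#' stays stochastic.
#'
#' @param labels integer (or factor) state sequence.
#' @param lag transition lag in samples (>= 1).
#' @return An object of class `markov_model` with the matrix `P`, the
#'   `lag`, and the state values `states`.
#' @export
transition_matrix <- function(labels, lag = 1L) {
  stopifnot(lag >= 1, length(labels) > lag)
  labels <- as.integer(factor(labels))
  states <- sort(unique(labels))
  ns <- length(states)
  from <- labels[seq_len(length(labels) - lag)]
  to <- labels[-seq_len(lag)]
  P <- matrix(0, ns, ns)
  cnt <- table(factor(from, levels = states), factor(to, levels = states))
  P[] <- as.numeric(cnt)
  rs <- rowSums(P)
  for (i in seq_len(ns)) {
    if (rs[i] == 0) P[i, i] <- 1 else P[i, ] <- P[i, ] / rs[i]
  }
  structure(list(P = P, lag = as.integer(lag), states = states,
                 counts = rs),
            class = "markov_model")
}

#' Spectral decomposition of a transition matrix
#'
#' Eigenpairs of the row-stochastic matrix sorted by descending real part.
#' The leading pair is the stationary one (eigenvalue 1, within numerical
#' tolerance); the slow eigenvectors define collective variables, with
#' implied relaxation timescales `t_i = -lag / log|Lambda_i|` for `i >= 2`
#' (this recovers the generator convention in which the leading eigenvalue
#' is 0). Right eigenvectors (functions of state) are returned for
#' projection; the stationary distribution comes from the leading left
#' eigenvector.
#'
#' @param model a [transition_matrix()] result.
#' @return List with `values`, `vectors` (right, columns matching
#'   `values`), `stationary`, `timescales`, and a `complex_pairs` flag.
#' @export
spectral_decomposition <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  e <- eigen(model$P)
  o <- order(Re(e$values), decreasing = TRUE)
  vals <- e$values[o]; vecs <- e$vectors[, o, drop = FALSE]
  if (abs(vals[1] - 1) > 1e-8)
    warning("leading eigenvalue deviates from 1 by ", abs(vals[1] - 1))
  el <- eigen(t(model$P))
  i1 <- which.min(abs(el$values - 1))
  pi0 <- Re(el$vectors[, i1]); pi0 <- pi0 / sum(pi0)
  ts <- rep(NA_real_, length(vals))
  if (length(vals) > 1) {
    lam <- Mod(vals[-1])
    ts[-1] <- ifelse(lam < 1 & lam > 0, -model$lag / log(lam), Inf)
  }
  cp <- any(abs(Im(vals)) > 1e-12)
  if (!cp) { vals <- Re(vals); vecs <- Re(vecs) }
  list(values = vals, vectors = vecs, stationary = pi0,
       timescales = ts, complex_pairs = cp)
}

#' Project a label sequence onto the slow eigenvector
#'
#' Per-frame value of the first non-trivial right eigenvector `phi2` at the
#' occupied microstate: the scalar slow reaction coordinate. The sign
#' convention is fixed so the longer-lived coarse state (larger mean run
#' length below vs above the midrange of the series) is negative, making
#' the output invariant to the arbitrary eigenvector sign.
#'
#' @param labels integer microstate sequence (1-based).
#' @param phi2 numeric vector indexed by microstate.
#' @return Numeric time series of `phi2` values.
#' @export
project_phi2 <- function(labels, phi2) {
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > length(phi2)))
    stop("label out of range of phi2")
  phi2 <- Re(phi2)
  series <- phi2[labels]
  thr <- mean(range(series))
  r <- rle(series > thr)
  up <- mean(r$lengths[r$values])
  dn <- mean(r$lengths[!r$values])
  if (is.finite(up) && is.finite(dn) && up > dn) series <- -series
  series
}

#' Two-state split by metastability maximization
#'
#' Scans thresholds on the slow coordinate; for each, builds the 2x2 coarse
#' transition matrix at the given lag and scores it by its trace (the sum
#' of self-transition probabilities, in (0, 2], equal to 2 for perfectly
#' metastable states and about 1 for structureless noise). Returns the
#' threshold maximizing the score, ties broken toward the series median.
#'
#' @param phi2_series numeric slow-coordinate series (non-constant).
#' @param candidate_thresholds thresholds to scan; default the 5%..95%
#'   quantiles.
#' @param lag coarse transition lag in samples.
#' @return An object of class `coarse_state`: `threshold`, integer
#'   `labels` (1 = below, 2 = above), and the metastability `score`.
#' @export
split_two_states <- function(phi2_series, candidate_thresholds = NULL,
                             lag = 1L) {
  x <- as.numeric(phi2_series)
  if (diff(range(x)) == 0) stop("series is constant")
  cand <- candidate_thresholds %||%
    unique(quantile(x, seq(0.05, 0.95, by = 0.05), names = FALSE))
  scores <- vapply(cand, function(thr) {
    lab <- as.integer(x > thr)
    if (length(unique(lab)) < 2) return(NA_real_)
    sum(diag(transition_matrix(lab + 1L, lag)$P))
  }, numeric(1))
  if (all(is.na(scores)))
    stop("every candidate threshold leaves a single occupied state")
  best <- max(scores, na.rm = TRUE)
  idx <- which(scores >= best - 1e-12)
  if (length(idx) > 1) idx <- idx[which.min(abs(cand[idx] - median(x)))]
  thr <- cand[idx]
  structure(list(threshold = thr, labels = as.integer(x > thr) + 1L,
                 score = scores[idx], candidate_scores = scores,
                 candidates = cand, lag = as.integer(lag)),
            class = "coarse_state")
}

#' @export
print.coarse_state <- function(x, ...) {
  cat("<coarse_state> threshold =", signif(x$threshold, 4),
      " metastability score =", round(x$score, 3), "\n")
  invisible(x)
}

#' End-to-end slow-mode extraction from multichannel series
#'
#' Convenience wrapper chaining [delay_embed()], [cluster_microstates()],
#' [transition_matrix()], [spectral_decomposition()], [project_phi2()] and
#' [split_two_states()].
#'
#' @param channels numeric matrix (time x channels).
#' @param K embedding depth.
#' @param lag transition lag in samples.
#' @param n_states number of microstates.
#' @param seed RNG seed for clustering.
#' @return List with `labels`, `markov`, `spectrum`, `phi2_series`, and the
#'   coarse `split`.
#' @export
metastable_pipeline <- function(channels, K = 11L, lag = 1L,
                                n_states = 100L, seed = 1L) {
  emb <- delay_embed(channels, K)
  cl <- cluster_microstates(emb, n_states, seed)
  mm <- transition_matrix(cl$labels, lag)
  sp <- spectral_decomposition(mm)
  phi2 <- sp$vectors[, 2]
  series <- project_phi2(cl$labels, phi2)
  split <- split_two_states(series, lag = lag)
  list(labels = cl$labels, markov = mm, spectrum = sp,
       phi2_series = series, split = split)
}
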