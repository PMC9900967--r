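#' Potential landscape specification
#'
#' A `potential_spec` bundles the fast-coordinate landscape `U(x, s)` together
#' with the slow-mode potential `V(s)`, the barrier height `deltaU(s)` between
#' the well minimum and the barrier top, its inverse, and the curvatures at
#' the well minimum and barrier top. These are the ingredients of the Kramers
#' escape rate and of the asymptotic first-passage-time and correlation
#' formulas.
#'
#' All functional fields must be vectorized in their first argument.
#'
#' @param U function `U(x, s)`, the landscape for the fast coordinate.
#' @param dUdx function `dUdx(x, s)`, the partial derivative of `U` in `x`.
#' @param V function `V(s)`, the potential confining the slow mode.
#' @param deltaU function `deltaU(s)`, barrier height as a function of `s`.
#' @param deltaU_inv function, inverse of `deltaU` on the branch `s >= 0`.
#' @param curvature_min function of `s`: second `x`-derivative of `U` at the
#'   well minimum.
#' @param curvature_barrier function of `s`: second `x`-derivative of `U` at
#'   the barrier top (negative).
#' @param kind character tag; `"quartic_double_well"` enables the compiled
#'   fast integration path.
#' @param mu_s slow-mode mean entering `V`.
#' @return An object of class `potential_spec`.
#' @seealso [double_well_potential()] for the default landscape.
#' @export
potential_spec <- function(U, dUdx, V, deltaU, deltaU_inv,
                           curvature_min, curvature_barrier,
                           kind = "custom", mu_s = 0) {
  stopifnot(is.function(U), is.function(dUdx), is.function(V),
            is.function(deltaU))
  structure(list(U = U, dUdx = dUdx, V = V, deltaU = deltaU,
                 deltaU_inv = deltaU_inv,
                 curvature_min = curvature_min,
                 curvature_barrier = curvature_barrier,
                 kind = kind, mu_s = mu_s),
            class = "potential_spec")
}

#' Quartic double-well landscape with slowly modulated barrier
#'
#' The default landscape `U(x, s) = s^2 (x^2 - 1)^2` has wells at `x = +/-1`
#' and a barrier at `x = 0` whose height `deltaU(s) = s^2` is set by the slow
#' mode, which itself relaxes in the quadratic potential
#' `V(s) = (s - mu_s)^2 / 2`. The curvatures at the extrema are
#' `8 s^2` (well) and `-4 s^2` (barrier), so the overdamped Kramers
#' prefactor is `(2 sqrt(2) / pi) s^2`.
#'
#' @param mu_s mean of the slow mode (default 0).
#' @return A [potential_spec()] with `kind = "quartic_double_well"`.
#' @export
double_well_potential <- function(mu_s = 0) {
  potential_spec(
    U = function(x, s) s^2 * (x^2 - 1)^2,
    dUdx = function(x, s) 4 * s^2 * x * (x^2 - 1),
    V = function(s) (s - mu_s)^2 / 2,
    deltaU = function(s) s^2,
    deltaU_inv = function(y) sqrt(y),
    curvature_min = function(s) 8 * s^2,
    curvature_barrier = function(s) -4 * s^2,
    kind = "quartic_double_well", mu_s = mu_s)
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$kind, "\n")
  cat("  mu_s =", x$mu_s, "\n")
  invisible(x)
}
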