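#' Natural cubic spline basis anchored at the left boundary
#'
#' Constructs a natural cubic spline basis for trial time (years since
#' randomization). The basis has `length(internal_knots) + 1` functions,
#' each of which is zero at the left boundary knot, cubic between knots,
#' twice continuously differentiable, and linear beyond both boundary
#' knots (the natural condition). With one internal knot this gives the
#' two time functions used for the nonlinear HbA1c response trajectory.
#'
#' Anchoring every basis function at the left boundary (t = 0,
#' randomization) means the trajectory value at baseline is carried
#' entirely by the intercept terms, so "change from baseline is zero at
#' t = 0" is an identifiable statement about the intercept alone.
#'
#' @param boundary_knots Numeric length-2, left and right boundary times
#'   in years (left < right).
#' @param internal_knots Numeric vector of knots strictly inside the
#'   boundary interval.
#' @return An object of class `ncs_basis` with elements `boundary_knots`,
#'   `internal_knots`, `knots` (all knots, ascending) and `df`.
#' @examples
#' b <- ncs_basis(c(0, 5), 2.5)
#' ncs_eval(b, c(0, 1, 2, 3))
#' @export
ncs_basis <- function(boundary_knots, internal_knots) {
  stopifnot(length(boundary_knots) == 2, is.numeric(boundary_knots),
            is.numeric(internal_knots), length(internal_knots) >= 1)
  boundary_knots <- sort(as.numeric(boundary_knots))
  internal_knots <- sort(as.numeric(internal_knots))
  if (any(internal_knots <= boundary_knots[1]) ||
      any(internal_knots >= boundary_knots[2])) {
    stop("internal knots must lie strictly inside the boundary interval",
         call. = FALSE)
  }
  structure(
    list(boundary_knots = boundary_knots,
         internal_knots = internal_knots,
         knots = c(boundary_knots[1], internal_knots, boundary_knots[2]),
         df = length(internal_knots) + 1L),
    class = "ncs_basis"
  )
}

#' @export
print.ncs_basis <- function(x, ...) {
  cat("Natural cubic spline basis (anchored at left boundary)\n")
  cat("  boundary knots:", format(x$boundary_knots), "\n")
  cat("  internal knots:", format(x$internal_knots), "\n")
  cat("  df:", x$df, "\n")
  invisible(x)
}

# truncated cubic (t - k)_+^3, vectorized over t
trunc_cubic <- function(t, k) pmax(t - k, 0)^3

#' Evaluate a natural cubic spline basis
#'
#' Returns the basis matrix at the requested times. Evaluation beyond the
#' boundary knots is permitted and is linear there by construction.
#'
#' @param basis An [ncs_basis()] object.
#' @param t Numeric vector of times (years).
#' @return Matrix with `length(t)` rows and `basis$df` columns.
#' @export
ncs_eval <- function(basis, t) {
  stopifnot(inherits(basis, "ncs_basis"), is.numeric(t))
  xi <- basis$knots
  M <- length(xi)
  rng <- xi[M] - xi[1]
  # d_j(t) = [(t - xi_j)_+^3 - (t - xi_M)_+^3] / (xi_M - xi_j), j = 1..M-1
  d <- function(j) {
    (trunc_cubic(t, xi[j]) - trunc_cubic(t, xi[M])) / (xi[M] - xi[j])
  }
  out <- matrix(0, length(t), basis$df)
  out[, 1] <- t - xi[1]
  if (M >= 3) {
    dlast <- d(M - 1)
    for (j in seq_len(M - 2)) out[, j + 1] <- (d(j) - dlast) / rng^2
  }
  colnames(out) <- paste0("ncs", seq_len(basis$df))
  out
}

#' Integrated natural cubic spline basis
#'
#' Exact antiderivatives of the basis functions: column j holds
#' \eqn{\int_0^t N_j(s) ds}. Each basis function is a combination of a
#' linear ramp and truncated cubics, so the integral is available in
#' closed form (truncated quartics); no quadrature is involved. Requires
#' a left boundary knot at 0 so that the integral starts at the time
#' origin.
#'
#' @inheritParams ncs_eval
#' @return Matrix with `length(t)` rows and `basis$df` columns; row of
#'   zeros at t = 0.
#' @export
ncs_integral <- function(basis, t) {
  stopifnot(inherits(basis, "ncs_basis"), is.numeric(t), all(t >= 0))
  xi <- basis$knots
  if (abs(xi[1]) > 1e-12) {
    stop("integrated basis requires the left boundary knot at 0", call. = FALSE)
  }
  M <- length(xi)
  rng <- xi[M] - xi[1]
  iq <- function(k) pmax(t - k, 0)^4 / 4   # int_0^t (s-k)_+^3 ds, k >= 0
  dint <- function(j) (iq(xi[j]) - iq(xi[M])) / (xi[M] - xi[j])
  out <- matrix(0, length(t), basis$df)
  out[, 1] <- t^2 / 2
  if (M >= 3) {
    dlast <- dint(M - 1)
    for (j in seq_len(M - 2)) out[, j + 1] <- (dint(j) - dlast) / rng^2
  }
  colnames(out) <- paste0("incs", seq_len(basis$df))
  out
}

#' Exact integral of a spline-represented trajectory
#'
#' Computes \eqn{\int_0^t \{c_0 + \sum_j c_j N_j(s)\} ds} exactly, the
#' quantity entering the cumulative-response hazard: the area under the
#' latent response trajectory up to time t.
#'
#' @inheritParams ncs_eval
#' @param coefs Numeric vector of length `basis$df`, coefficients on the
#'   spline basis functions.
#' @param t Numeric vector of times (years), all nonnegative.
#' @param intercept Scalar added constant (the trajectory value carried
#'   by intercept-like terms: fixed intercept, baseline covariate effect
#'   and random intercept).
#' @return Numeric vector of integrals, one per time; 0 at t = 0.
#' @export
ncs_antiderivative <- function(basis, coefs, t, intercept = 0) {
  stopifnot(length(coefs) == basis$df, length(intercept) == 1)
  drop(intercept * t + ncs_integral(basis, t) %*% coefs)
}

#' Cubic B-spline basis for the log baseline hazard
#'
#' A clamped cubic B-spline basis on the follow-up interval, used to
#' model the log baseline hazard flexibly (five internal knots by
#' default placement elsewhere in the package). Rows form a partition of
#' unity; evaluation outside the boundary clamps to the boundary value.
#'
#' @param boundary_knots Numeric length-2 interval.
#' @param internal_knots Knots strictly inside the interval.
#' @param degree Spline degree (cubic by default).
#' @return An object of class `bspline_basis` with a `df` element equal
#'   to `length(internal_knots) + degree + 1`.
#' @export
bspline_basis <- function(boundary_knots, internal_knots, degree = 3L) {
  stopifnot(length(boundary_knots) == 2, degree >= 1)
  boundary_knots <- sort(as.numeric(boundary_knots))
  internal_knots <- sort(as.numeric(internal_knots))
  if (length(internal_knots) &&
      (any(internal_knots <= boundary_knots[1]) ||
       any(internal_knots >= boundary_knots[2]))) {
    stop("internal knots must lie strictly inside the boundary interval",
         call. = FALSE)
  }
  structure(
    list(boundary_knots = boundary_knots,
         internal_knots = internal_knots,
         degree = as.integer(degree),
         df = length(internal_knots) + degree + 1L),
    class = "bspline_basis"
  )
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat("Clamped B-spline basis, degree", x$degree, "\n")
  cat("  boundary knots:", format(x$boundary_knots), "\n")
  cat("  internal knots:", format(x$internal_knots), "\n")
  cat("  df:", x$df, "\n")
  invisible(x)
}

#' Evaluate a B-spline basis
#'
#' @param basis A [bspline_basis()] object.
#' @param t Numeric vector of times; values outside the boundary are
#'   clamped to the nearest boundary knot.
#' @return Matrix with `length(t)` rows and `basis$df` columns; each row
#'   is nonnegative and sums to 1.
#' @export
bspline_eval <- function(basis, t) {
  stopifnot(inherits(basis, "bspline_basis"), is.numeric(t))
  b <- basis$boundary_knots
  t <- pmin(pmax(t, b[1]), b[2])
  ord <- basis$degree + 1L
  kv <- c(rep(b[1], ord), basis$internal_knots, rep(b[2], ord))
  out <- splines::splineDesign(kv, t, ord = ord)
  colnames(out) <- paste0("bs", seq_len(basis$df))
  out
}
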