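#' Lumped fluidic-circuit parameters
#'
#' Collects the discrete elements of the coflow circuit: the blood-channel
#' resistance `R_b1 = 12 mu_b l1 / (w h^3)`, the reference-viscosity scale
#' resistance of the coflowing channel `R_r3 = 12 mu_r l2 / (w h^3)`, the
#' two compliances (C1: inlet tubing + PDMS channel, C2: RBC elasticity),
#' and the linearization constant CF0. The model requires C1 < C2: the
#' elastic storage of the cellular phase dominates that of the hardware.
#'
#' @param geometry a [channel_geometry()].
#' @param fluids a [fluid_pair()] (mu_b required).
#' @param C1,C2 compliances, um^3/mPa, with C1 < C2.
#' @param CF0 linearization constant (see [cf0_constant()]); defaults to the
#'   shipped value for the geometry's depth when available.
#' @return an object of class `"circuit_parameters"`.
#' @examples
#' geom <- channel_geometry(h = 20)
#' circuit_parameters(geom, fluid_pair(1, 2.2266), C1 = 53.3, C2 = 1398.2)
#' @export
circuit_parameters <- function(geometry, fluids, C1, C2, CF0 = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"), inherits(fluids, "fluid_pair"))
  if (is.null(CF0)) {
    key <- as.character(geometry$h)
    if (!key %in% names(.BUILTIN_CF)) {
      stop("no shipped CF0 for this depth; supply 'CF0'", call. = FALSE)
    }
    CF0 <- .BUILTIN_CF[[key]]$cf0
  }
  .check_positive(C1 = C1, C2 = C2, CF0 = CF0)
  if (C1 >= C2) stop("model requires C1 < C2", call. = FALSE)
  structure(list(
    geometry = geometry, fluids = fluids, C1 = C1, C2 = C2, CF0 = CF0,
    R_b1 = rect_resistance(fluids$mu_b, geometry$l1, geometry$w, geometry$h),
    R_r3 = rect_resistance(fluids$mu_r, geometry$l2, geometry$w, geometry$h)
  ), class = "circuit_parameters")
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("Coflow circuit parameters:\n")
  cat(sprintf("  R_b1 = %.4g, R_r3 = %.4g mPa.s/um^3\n", x$R_b1, x$R_r3))
  cat(sprintf("  C1 = %.4g, C2 = %.4g um^3/mPa; CF0 = %.4g\n", x$C1, x$C2, x$CF0))
  cat(sprintf("  mu_r = %g, mu_b = %g mPa.s; h = %g um\n",
              x$fluids$mu_r, x$fluids$mu_b, x$geometry$h))
  invisible(x)
}

#' Coefficients of the linearized governing equation
#'
#' The reciprocal interface coordinate beta = 1/(1 - alpha) obeys
#' `a beta'' + b beta' + c beta = c + Q_b/Q_r` once the correction factor
#' is frozen at CF0, with
#' `a = R_b1 R_r3 C1 C2`, `b = R_r3 (C1 + C2 + C1 (l1/l2) CF0)`,
#' `c = (mu_r/mu_b) CF0`.
#'
#' @param params a [circuit_parameters()].
#' @return named numeric vector `c(a, b, c)`.
#' @export
characteristic_coefficients <- function(params) {
  stopifnot(inherits(params, "circuit_parameters"))
  g <- params$geometry
  c(a = params$R_b1 * params$R_r3 * params$C1 * params$C2,
    b = params$R_r3 * (params$C1 + params$C2 +
                         params$C1 * (g$l1 / g$l2) * params$CF0),
    c = (params$fluids$mu_r / params$fluids$mu_b) * params$CF0)
}

#' @rdname eigenvalues_forward
#' @param a,b,c coefficients of the characteristic quadratic
#'   `a lambda^2 - b lambda + c = 0` (see [characteristic_coefficients()]).
#' @param tie_tol relative discriminant tolerance below which the roots are
#'   declared repeated.
#' @export
eigenvalues_from_coefficients <- function(a, b, c, tie_tol = 1e-12) {
  .check_positive(a = a, b = b, c = c)
  disc <- b^2 - 4 * a * c
  if (disc < 0) {
    stop("underdamped system (negative discriminant): the two-compliance ",
         "model requires two real decay modes", call. = FALSE)
  }
  s <- sqrt(disc)
  lam <- c(lambda1 = (b + s) / (2 * a), lambda2 = (b - s) / (2 * a))
  repeated <- disc <= tie_tol * b^2
  if (repeated) {
    warning("repeated decay rates (discriminant ~ 0): modes are not distinguishable",
            call. = FALSE)
  }
  attr(lam, "repeated") <- repeated
  lam
}

#' Decay rates of the two interface relaxation modes
#'
#' Roots of `a lambda^2 - b lambda + c = 0`, ordered lambda1 >= lambda2 > 0.
#' They satisfy the sum and product relations
#' `lambda1 + lambda2 = (C1 + C2 + C1 (l1/l2) CF0) / (R_b1 C1 C2)` and
#' `lambda1 * lambda2 = (mu_r/mu_b) CF0 / (R_b1 R_r3 C1 C2)`.
#' A repeated root (discriminant zero to within relative 1e-12) is flagged
#' with a warning and the attribute `"repeated"`; downstream compliance
#' inversion rejects such systems.
#'
#' @param params a [circuit_parameters()].
#' @return named numeric vector `c(lambda1, lambda2)` in 1/s.
#' @export
eigenvalues_forward <- function(params) {
  co <- characteristic_coefficients(params)
  eigenvalues_from_coefficients(co[["a"]], co[["b"]], co[["c"]])
}

#' Two-exponential interface transient
#'
#' Evaluates `beta(t) = d1 exp(-lambda1 t) + d2 exp(-lambda2 t) + 1`, the
#' general switch-off solution of the linearized governing equation.
#'
#' @param t times, s (vectorized).
#' @param d1,d2 mode amplitudes.
#' @param lambda1,lambda2 decay rates, 1/s.
#' @return beta values.
#' @seealso [alpha_from_beta()] to map back to the interface fraction.
#' @export
analytic_beta <- function(t, d1, d2, lambda1, lambda2) {
  .check_positive(lambda1 = lambda1, lambda2 = lambda2)
  d1 * exp(-lambda1 * t) + d2 * exp(-lambda2 * t) + 1
}

#' Interface fraction from its reciprocal coordinate
#'
#' `alpha = 1 - 1/beta` for beta > 1. Values beta <= 1 mean the blood
#' stream is fully washed out; these map to alpha = 0 and are flagged via
#' the `"washed_out"` attribute.
#'
#' @param beta reciprocal interface coordinate.
#' @return alpha values with attribute `"washed_out"` (logical vector).
#' @export
alpha_from_beta <- function(beta) {
  washed <- beta <= 1
  a <- ifelse(washed, 0, 1 - 1 / beta)
  attr(a, "washed_out") <- washed
  a
}

#' Mode amplitudes after pump switch-off
#'
#' At switch-off the node pressures are continuous, so the interface starts
#' from its steady value with zero slope: beta(0) = beta0, beta'(0) = 0.
#' This fixes the amplitudes `d1 = -lambda2 (beta0 - 1)/(lambda1 - lambda2)`
#' and `d2 = lambda1 (beta0 - 1)/(lambda1 - lambda2)`.
#'
#' @param beta0 steady beta just before switch-off (> 1 unless at rest).
#' @param params optional [circuit_parameters()] used to compute the decay
#'   rates when `lambdas` is not given.
#' @param lambdas optional numeric `c(lambda1, lambda2)`.
#' @return named numeric vector `c(d1, d2)`.
#' @export
turnoff_solution <- function(beta0, params = NULL, lambdas = NULL) {
  if (is.null(lambdas)) {
    if (is.null(params)) stop("supply 'params' or 'lambdas'", call. = FALSE)
    lambdas <- eigenvalues_forward(params)
  }
  l1 <- lambdas[[1]]; l2 <- lambdas[[2]]
  if (isTRUE(attr(lambdas, "repeated")) || l1 == l2) {
    stop("repeated decay rates: the two-mode switch-off solution is undefined",
         call. = FALSE)
  }
  if (beta0 < 1) stop("'beta0' must be >= 1", call. = FALSE)
  c(d1 = -l2 * (beta0 - 1) / (l1 - l2),
    d2 =  l1 * (beta0 - 1) / (l1 - l2))
}

# general linear-phase propagator: amplitudes for beta(t) relaxing from
# (beta0, dbeta0) toward beta_target with the given modes
phase_amplitudes <- function(beta0, dbeta0, beta_target, lambda1, lambda2) {
  if (lambda1 == lambda2) stop("repeated decay rates", call. = FALSE)
  delta <- beta0 - beta_target
  d1 <- (lambda2 * delta + dbeta0) / (lambda2 - lambda1)
  c(d1 = d1, d2 = delta - d1)
}
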