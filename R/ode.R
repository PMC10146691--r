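#' Steady-state interface position
#'
#' Inverts the steady-state law `mu_b = mu_r * CF(alpha) * alpha/(1-alpha) *
#' Qr/Qb` for alpha by bracketed root finding over the correction-factor
#' model's validity range. The root is unique whenever
#' `CF(alpha) * alpha/(1-alpha)` is monotone there; if several roots exist
#' they are all reported in the error.
#'
#' @param mu_b test-fluid viscosity, mPa.s.
#' @param flow_ratio blood-to-reference flow ratio Qb/Qr.
#' @param mu_r reference viscosity, mPa.s.
#' @param cf_model a [cf_model()].
#' @return the interface fraction alpha.
#' @examples
#' steady_interface(3, 1, 1, cf_constant(1)) # 0.75
#' @export
steady_interface <- function(mu_b, flow_ratio = 1, mu_r = 1, cf_model) {
  .check_positive(mu_b = mu_b, flow_ratio = flow_ratio, mu_r = mu_r)
  stopifnot(inherits(cf_model, "cf_model"))
  f <- function(a) mu_r * cf_eval(cf_model, a) * a / (1 - a) / flow_ratio - mu_b
  lo <- cf_model$range[1]; hi <- cf_model$range[2]
  grid <- seq(lo, hi, length.out = 801)
  fg <- f(grid)
  sgn <- sign(fg)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(fg == 0)
  if (length(flips) + length(exact) == 0) {
    stop(sprintf("no steady interface in [%g, %g] for mu_b = %g", lo, hi, mu_b),
         call. = FALSE)
  }
  roots <- c(grid[exact],
             vapply(flips, function(i) {
               uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
             }, numeric(1)))
  roots <- sort(unique(roots))
  if (length(roots) > 1) {
    stop(sprintf("multiple steady interfaces (non-monotone CF product): %s",
                 paste(signif(roots, 8), collapse = ", ")), call. = FALSE)
  }
  roots
}

# right-hand side of the full nonlinear interface equation, state (alpha, alpha')
.coflow_rhs <- function(t, y, parms) {
  a <- y[1]; da <- y[2]
  one_m <- 1 - a
  cf <- cf_eval(parms$cf, a)
  cfp <- cf_eval(parms$cf, a, deriv = 1)
  g <- a * cf / one_m
  gp <- ((cf + a * cfp) * one_m + a * cf) / one_m^2
  dda <- (parms$forcing - parms$mu_ratio * g -
            (parms$B / one_m^2 + parms$D * gp) * da -
            2 * parms$A * da^2 / one_m^3) * one_m^2 / parms$A
  list(c(da, dda))
}

#' Integrate the full nonlinear interface equation
#'
#' Numerically integrates the second-order nonlinear governing equation for
#' the interface (with the alpha-dependent polynomial correction factor, no
#' linearization), phase by phase over the square-wave flow program. Serves
#' as the oracle against which the linearized analytic solution is checked.
#' The state is (alpha, alpha'); integration uses an adaptive
#' implicit-capable solver (lsodar; the two well-separated decay modes make
#' the system mildly stiff) with relative tolerance 1e-8 and absolute
#' tolerance 1e-10, and halts with a diagnostic if alpha leaves the
#' correction-factor validity range.
#'
#' @param params a [circuit_parameters()].
#' @param cf_model a [cf_model()]; its CF0 is ignored here (the full
#'   polynomial is used).
#' @param program a [flow_program()].
#' @param t_span optional `c(from, to)` restriction, s.
#' @param alpha0 initial interface fraction; defaults to the steady value
#'   for the on-phase flow ratio.
#' @param dalpha0 initial slope, 1/s.
#' @return an [interface_series()]; if integration was halted the attribute
#'   `"truncated"` carries the stop time.
#' @export
simulate_nonlinear <- function(params, cf_model, program, t_span = NULL,
                               alpha0 = NULL, dalpha0 = 0) {
  stopifnot(inherits(params, "circuit_parameters"),
            inherits(cf_model, "cf_model"),
            inherits(program, "flow_program"))
  if (is.null(alpha0)) {
    alpha0 <- steady_interface(params$fluids$mu_b,
                               program$Q0 / program$Qr,
                               params$fluids$mu_r, cf_model)
  }
  lo <- cf_model$range[1]; hi <- cf_model$range[2]
  if (alpha0 <= lo || alpha0 >= hi) {
    stop("initial alpha outside the correction-factor validity range",
         call. = FALSE)
  }
  g <- params$geometry
  parms <- list(
    A = params$R_b1 * params$R_r3 * params$C1 * params$C2,
    B = (params$C1 + params$C2) * params$R_r3,
    D = params$R_r3 * params$C1 * g$l1 / g$l2,
    mu_ratio = params$fluids$mu_r / params$fluids$mu_b,
    cf = cf_model, forcing = 0)

  times <- program_times(program)
  if (!is.null(t_span)) times <- times[times >= t_span[1] & times <= t_span[2]]
  if (length(times) < 2) stop("time span contains fewer than 2 samples", call. = FALSE)

  # integrate segment-wise between pump switches so the forcing is smooth
  bounds <- sort(unique(c(times[1], program$switch_times, times[length(times)])))
  bounds <- bounds[bounds >= times[1] & bounds <= times[length(times)]]
  rootfun <- function(t, y, parms) c(y[1] - lo, hi - y[1])
  y <- c(alpha0, dalpha0)
  out_t <- numeric(0); out_a <- numeric(0)
  truncated <- NA_real_
  for (i in seq_len(length(bounds) - 1)) {
    seg <- c(bounds[i], bounds[i + 1])
    seg_times <- unique(c(seg[1], times[times > seg[1] & times < seg[2]], seg[2]))
    parms$forcing <- Qb_at(program, seg[1]) / program$Qr
    sol <- deSolve::ode(y = y, times = seg_times, func = .coflow_rhs,
                        parms = parms, method = "lsodar", rtol = 1e-8,
                        atol = 1e-10, rootfunc = rootfun)
    keep <- sol[, 1] %in% times
    out_t <- c(out_t, sol[keep, 1]); out_a <- c(out_a, sol[keep, 2])
    if (!is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0) {
      truncated <- attr(sol, "troot")[1]
      warning(sprintf(
        "integration halted at t = %.3f s: alpha reached the validity boundary",
        truncated), call. = FALSE)
      break
    }
    y <- as.numeric(sol[nrow(sol), 2:3])
  }
  dup <- duplicated(out_t)
  ser <- interface_series(out_t[!dup], pmin(pmax(out_a[!dup], 1e-12), 1 - 1e-12),
                          program = program)
  attr(ser, "truncated") <- truncated
  ser
}
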