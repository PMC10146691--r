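#' Select the settled portion of each on-phase
#'
#' After the blood pump switches on, the interface needs time to settle;
#' viscosity is read from the tail of the on-phase. This takes the last `n`
#' samples of every on-phase, excluding everything within `settle` seconds
#' of the switch-on.
#'
#' @param series an [interface_series()].
#' @param program a [flow_program()]; defaults to the one attached to the
#'   series.
#' @param n samples per window (default 50).
#' @param settle settling time after switch-on, s (default 70).
#' @return a data.frame with columns `cycle`, `time_s`, `alpha_b`.
#' @export
select_steady_window <- function(series, program = NULL, n = 50, settle = 70) {
  if (is.null(program)) program <- attr(series, "program")
  if (is.null(program)) stop("no flow program available", call. = FALSE)
  t_on <- program$t_on
  if (t_on < settle + n * program$dt) {
    stop(sprintf(
      "on-phase (%g s) shorter than settling time + window (%g s): insufficient data",
      t_on, settle + n * program$dt), call. = FALSE)
  }
  out <- lapply(seq_len(program$cycles) - 1L, function(i) {
    start <- i * program$T_period
    idx <- which(series$time_s >= start + t_on - n * program$dt &
                   series$time_s < start + t_on)
    if (length(idx) == 0) return(NULL)
    data.frame(cycle = i + 1L, time_s = series$time_s[idx],
               alpha_b = series$alpha_b[idx])
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    stop("series contains no settled on-phase samples: insufficient data",
         call. = FALSE)
  }
  out
}

#' Blood viscosity from the steady interface
#'
#' Applies the steady-state law `mu_b = mu_r * CF(alpha) * alpha/(1-alpha) *
#' Qr/Qb` at the (window-averaged) interface fraction.
#'
#' @param alpha steady interface fraction.
#' @param Q_r,Q_b reference and blood flow rates (any common unit).
#' @param mu_r reference viscosity, mPa.s.
#' @param cf_model a [cf_model()].
#' @return mu_b in mPa.s; if alpha lies outside the validity range the
#'   value carries attribute `"validity_warning"`.
#' @export
steady_viscosity <- function(alpha, Q_r, Q_b, mu_r, cf_model) {
  .check_positive(Q_r = Q_r, Q_b = Q_b, mu_r = mu_r)
  stopifnot(inherits(cf_model, "cf_model"))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  mu <- mu_r * cf_eval(cf_model, alpha) * alpha / (1 - alpha) * (Q_r / Q_b)
  if (alpha < cf_model$range[1] || alpha > cf_model$range[2]) {
    warning("steady alpha outside the correction-factor validity range",
            call. = FALSE)
    attr(mu, "validity_warning") <- TRUE
  }
  mu
}

# tail log-linear fit + residual peeling initializer for the two-mode decay
.peel_init <- function(t, y) {
  n <- length(t)
  tail_idx <- seq(max(1, floor(0.6 * n)), n)
  pos <- tail_idx[y[tail_idx] > 0]
  if (length(pos) < 5) return(NULL)
  f2 <- lm(log(y[pos]) ~ t[pos])
  l2 <- -coef(f2)[[2]]; d2 <- exp(coef(f2)[[1]])
  if (!is.finite(l2) || l2 <= 0) return(NULL)
  r <- y - d2 * exp(-l2 * t)
  head_idx <- seq_len(max(5, floor(0.25 * n)))
  big <- head_idx[abs(r[head_idx]) > max(abs(r)) * 0.05]
  if (length(big) < 4) return(NULL)
  sgn <- sign(sum(r[big]))
  if (sgn == 0) return(NULL)
  f1 <- lm(log(abs(r[big])) ~ t[big])
  l1 <- -coef(f1)[[2]]; d1 <- sgn * exp(coef(f1)[[1]])
  if (!is.finite(l1) || l1 <= 0 || l1 <= l2) return(NULL)
  c(d1 = d1, d2 = d2, l1 = l1, l2 = l2)
}

# variable projection: best amplitudes and weighted RSS for fixed decay rates
.vp_rss <- function(t, y, w, l1, l2) {
  X <- cbind(exp(-l1 * t), exp(-l2 * t)) * sqrt(w)
  fit <- tryCatch(lm.fit(X, y * sqrt(w)), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf))
  list(rss = sum(fit$residuals^2), d = fit$coefficients)
}

#' Two-exponential fit of the switch-off decay
#'
#' Nonlinear least squares of `beta - 1 = d1 exp(-lambda1 t) + d2
#' exp(-lambda2 t)` against the post-switch-off samples, with time re-zeroed
#' at the switch-off instant. Initialization peels the slow mode off a tail
#' log-linear fit; if peeling fails, a log-spaced grid of decay-rate pairs
#' (best amplitudes by linear least squares) seeds the optimizer. Decay
#' rates are reported in canonical order lambda1 >= lambda2.
#'
#' Observation noise lives on alpha, so the induced noise on beta - 1
#' scales as beta^2; by default the least squares are weighted with
#' `(1 - alpha)^4` (inverse variance), which makes the fit equivalent to
#' maximum likelihood on alpha to first order. Set `weighted = FALSE` for
#' plain unweighted least squares on beta - 1.
#'
#' @param series an [interface_series()] (samples at `time_s >= t0` are
#'   used), or a data.frame with `time_s` and `alpha_b`.
#' @param t0 switch-off time, s.
#' @param t_max optional upper limit (absolute time, s) of the fit window.
#' @param min_points minimum number of usable samples (default 40).
#' @param weighted use inverse-variance weights (default TRUE).
#' @return an object of class `"eigen_fit"`: list with `d1`, `d2`,
#'   `lambda1`, `lambda2`, `rss`, `n`, `converged`, `degenerate`, `t0`,
#'   and the fitted data.
#' @export
two_exponential_fit <- function(series, t0 = 0, t_max = Inf, min_points = 40,
                                weighted = TRUE) {
  idx <- which(series$time_s >= t0 & series$time_s <= t_max)
  if (length(idx) < min_points) {
    stop(sprintf("need at least %d post-switch-off samples, have %d",
                 min_points, length(idx)), call. = FALSE)
  }
  t <- series$time_s[idx] - t0
  alpha <- series$alpha_b[idx]
  y <- 1 / (1 - alpha) - 1
  w <- if (weighted) (1 - alpha)^4 else rep(1, length(t))

  init <- .peel_init(t, y)
  fit <- NULL
  if (!is.null(init)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d1 * exp(-l1 * t) + d2 * exp(-l2 * t),
        start = as.list(init), weights = w,
        lower = c(-Inf, -Inf, 1e-8, 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 1000, ptol = 1e-10)),
      error = function(e) NULL)
  }
  ok <- function(f) {
    !is.null(f) && all(is.finite(coef(f))) && coef(f)[["l1"]] > 0 &&
      coef(f)[["l2"]] > 0
  }
  if (!ok(fit)) {
    # multi-start over a log-spaced rate grid with projected amplitudes
    rates <- 10^seq(-3.5, 0.5, length.out = 25)
    best <- NULL; best_rss <- Inf
    for (i in seq_along(rates)) for (j in seq_len(i - 1)) {
      v <- .vp_rss(t, y, w, rates[i], rates[j])
      if (v$rss < best_rss) {
        best_rss <- v$rss
        best <- c(d1 = unname(v$d[1]), d2 = unname(v$d[2]),
                  l1 = rates[i], l2 = rates[j])
      }
    }
    if (is.null(best)) stop("two-exponential fit failed to initialize", call. = FALSE)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d1 * exp(-l1 * t) + d2 * exp(-l2 * t),
        start = as.list(best), weights = w,
        lower = c(-Inf, -Inf, 1e-8, 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 1000, ptol = 1e-10)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    # two-mode fit unidentifiable (e.g. effectively single-exponential
    # data): fall back to one mode and flag the result as degenerate
    tail_fit <- lm(log(pmax(y, 1e-12)) ~ t, weights = w)
    s1 <- list(d2 = exp(coef(tail_fit)[[1]]), l2 = max(-coef(tail_fit)[[2]], 1e-6))
    fit1 <- tryCatch(
      minpack.lm::nlsLM(y ~ d2 * exp(-l2 * t), start = s1, weights = w,
                        lower = c(-Inf, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit1)) stop("two-exponential fit did not converge", call. = FALSE)
    co1 <- coef(fit1)
    return(structure(list(
      d1 = 0, d2 = co1[["d2"]], lambda1 = co1[["l2"]], lambda2 = co1[["l2"]],
      rss = sum(resid(fit1)^2), n = length(t),
      converged = fit1$convInfo$isConv, degenerate = TRUE, t0 = t0,
      t = t, beta_minus_1 = y,
      fitted = co1[["d2"]] * exp(-co1[["l2"]] * t)
    ), class = "eigen_fit"))
  }
  co <- coef(fit)
  converged <- fit$convInfo$isConv && all(is.finite(co))
  if (co[["l1"]] <= 0 || co[["l2"]] <= 0) {
    stop("fit rejected: non-positive decay rate estimate", call. = FALSE)
  }
  # canonical ordering lambda1 >= lambda2
  if (co[["l1"]] < co[["l2"]]) {
    co <- c(d1 = co[["d2"]], d2 = co[["d1"]], l1 = co[["l2"]], l2 = co[["l1"]])
  }
  degenerate <- (co[["l1"]] - co[["l2"]]) < 1e-3 * co[["l1"]] ||
    abs(co[["d1"]]) < 1e-6 * max(abs(co[["d2"]]), 1e-12)
  structure(list(
    d1 = co[["d1"]], d2 = co[["d2"]],
    lambda1 = co[["l1"]], lambda2 = co[["l2"]],
    rss = sum(resid(fit)^2), n = length(t),
    converged = converged, degenerate = degenerate,
    t0 = t0, t = t, beta_minus_1 = y,
    fitted = co[["d1"]] * exp(-co[["l1"]] * t) + co[["d2"]] * exp(-co[["l2"]] * t)
  ), class = "eigen_fit")
}

#' @export
print.eigen_fit <- function(x, ...) {
  cat("Two-exponential switch-off fit (beta - 1):\n")
  cat(sprintf("  d1 = %.5g, d2 = %.5g\n", x$d1, x$d2))
  cat(sprintf("  lambda1 = %.5g 1/s, lambda2 = %.5g 1/s\n", x$lambda1, x$lambda2))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s%s\n", x$n, x$rss,
              x$converged, if (x$degenerate) " (degenerate: single mode)" else ""))
  invisible(x)
}

# shared pieces of the eigenvalue system in terms of geometry/CF0:
# r = R_b1 per unit viscosity, G = mu_r*CF0/(r*R_r3*lambda1*lambda2),
# k = 1 + (l1/l2)*CF0
.eigen_system <- function(lambda1, lambda2, geom, mu_r, CF0) {
  if (!(lambda1 > lambda2 && lambda2 > 0)) {
    stop("need lambda1 > lambda2 > 0 (two distinct decay modes)", call. = FALSE)
  }
  r <- 12 * geom$l1 / (geom$w * geom$h^3)
  R_r3 <- 12 * mu_r * geom$l2 / (geom$w * geom$h^3)
  list(S = lambda1 + lambda2, P = lambda1 * lambda2, r = r, R_r3 = R_r3,
       k = 1 + (geom$l1 / geom$l2) * CF0,
       G = mu_r * CF0 / (r * R_r3 * lambda1 * lambda2))
}

# solve q2 x^2 + q1 x + q0 = 0, returning real roots (possibly empty)
.real_quad_roots <- function(q2, q1, q0) {
  disc <- q1^2 - 4 * q2 * q0
  if (disc < 0) return(numeric(0))
  s <- sqrt(disc)
  sort(c((-q1 - s) / (2 * q2), (-q1 + s) / (2 * q2)))
}

#' Compliances from the fitted decay rates
#'
#' Solves the eigenvalue sum and product relations for (C1, C2) given the
#' blood viscosity. Writing S = lambda1 + lambda2, P = lambda1*lambda2,
#' k = 1 + (l1/l2) CF0, the product relation fixes Pi = C1*C2 and the sum
#' relation fixes k*C1 + C2, leaving the quadratic
#' `k C1^2 - (S R_b1 Pi) C1 + Pi = 0`; the root with C1 < C2 = Pi/C1 is
#' physical.
#'
#' The two roots always pair as (C1, C2) and (C2/k, k*C1), so when
#' C2 < k^2 C1 both candidates satisfy C1 < C2 and the decay rates alone
#' cannot distinguish them; the root with the stronger separation (the
#' smaller C1, matching the working assumption that the cellular compliance
#' dominates the hardware compliance) is returned, and both candidates are
#' always reported.
#'
#' @param lambda1,lambda2 decay rates, 1/s, lambda1 > lambda2.
#' @param mu_b blood viscosity, mPa.s.
#' @param geom a [channel_geometry()].
#' @param mu_r reference viscosity, mPa.s.
#' @param CF0 linearization constant.
#' @return named numeric `c(C1, C2)` in um^3/mPa, with both candidate roots
#'   in attribute `"candidates"`.
#' @examples
#' compliances_from_eigenvalues(0.1949047, 0.01267584, 2.2266,
#'                              channel_geometry(h = 20), 1, 1.183)
#' @export
compliances_from_eigenvalues <- function(lambda1, lambda2, mu_b, geom,
                                         mu_r = 1, CF0) {
  .check_positive(mu_b = mu_b, mu_r = mu_r, CF0 = CF0)
  sys <- .eigen_system(lambda1, lambda2, geom, mu_r, CF0)
  Pi <- sys$G / mu_b^2              # C1*C2
  Sig <- sys$S * (sys$r * mu_b) * Pi  # k*C1 + C2
  roots <- .real_quad_roots(sys$k, -Sig, Pi)
  roots <- roots[roots > 0]
  if (length(roots) == 0) {
    stop("compliances not identifiable from these decay rates (no real ",
         "positive root)", call. = FALSE)
  }
  cand <- lapply(roots, function(C1) c(C1 = C1, C2 = Pi / C1))
  phys <- Filter(function(p) p[["C1"]] < p[["C2"]], cand)
  if (length(phys) == 0) {
    stop("model inconsistency: no root satisfies C1 < C2", call. = FALSE)
  }
  out <- phys[[1]]
  attr(out, "candidates") <- do.call(rbind, cand)
  out
}

#' Complete the parameter set from the decay rates and one known quantity
#'
#' The eigenvalue sum and product relations link three unknowns (mu_b, C1,
#' C2) through two equations; supplying any one of them determines the
#' other two. Each case reduces to a quadratic (in C1 when mu_b is known,
#' in mu_b otherwise); the physical root is selected by mu_b > 0, C1, C2 > 0
#' and C1 < C2, and both candidate roots are reported in the
#' `"candidates"` attribute.
#'
#' @param lambda1,lambda2 decay rates, 1/s, lambda1 > lambda2.
#' @param known a single named value: one of `c(mu_b = ...)`,
#'   `c(C1 = ...)`, `c(C2 = ...)`.
#' @param geom a [channel_geometry()].
#' @param mu_r reference viscosity, mPa.s.
#' @param CF0 linearization constant.
#' @return named numeric `c(mu_b, C1, C2)` with attribute `"candidates"`.
#' @examples
#' complete_parameter_set(0.1945, 0.0127, c(C2 = 1398.2),
#'                        channel_geometry(h = 20), 1, 1.183)
#' @export
complete_parameter_set <- function(lambda1, lambda2, known, geom,
                                   mu_r = 1, CF0) {
  if (length(known) != 1 || is.null(names(known)) ||
      !names(known) %in% c("mu_b", "C1", "C2")) {
    stop("'known' must be a single named value: mu_b, C1 or C2", call. = FALSE)
  }
  .check_positive(known = unname(known), mu_r = mu_r, CF0 = CF0)
  sys <- .eigen_system(lambda1, lambda2, geom, mu_r, CF0)
  what <- names(known); val <- unname(known)

  if (what == "mu_b") {
    cc <- compliances_from_eigenvalues(lambda1, lambda2, val, geom, mu_r, CF0)
    out <- c(mu_b = val, cc)
    attr(out, "candidates") <- attr(cc, "candidates")
    return(out)
  }
  # with C1 known: k*C1*mu^2 - r*S*G*mu + G/C1 = 0, then C2 = G/(C1*mu^2)
  # with C2 known: C2*mu^2 - r*S*G*mu + k*G/C2 = 0, then C1 = G/(C2*mu^2)
  if (what == "C1") {
    mu_roots <- .real_quad_roots(sys$k * val, -sys$r * sys$S * sys$G,
                                 sys$G / val)
    cand <- lapply(mu_roots[mu_roots > 0], function(mu) {
      c(mu_b = mu, C1 = val, C2 = sys$G / (val * mu^2))
    })
  } else {
    mu_roots <- .real_quad_roots(val, -sys$r * sys$S * sys$G,
                                 sys$k * sys$G / val)
    cand <- lapply(mu_roots[mu_roots > 0], function(mu) {
      c(mu_b = mu, C1 = sys$G / (val * mu^2), C2 = val)
    })
  }
  if (length(cand) == 0) {
    stop("no real positive root: decay rates inconsistent with the supplied ",
         "parameter", call. = FALSE)
  }
  phys <- Filter(function(p) p[["C1"]] < p[["C2"]], cand)
  if (length(phys) == 0) {
    stop("model inconsistency: no root satisfies C1 < C2", call. = FALSE)
  }
  out <- phys[[1]]
  attr(out, "candidates") <- do.call(rbind, cand)
  out
}
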