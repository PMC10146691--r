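#' Fit the two-compliance coflow model to an interface series
#'
#' The end-to-end inverse pipeline. For every on/off cycle of the flow
#' program:
#' \enumerate{
#'   \item the settled tail of the on-phase is selected
#'     ([select_steady_window()]) and its mean interface fraction inverted
#'     for the blood viscosity through the steady-state law
#'     ([steady_viscosity()]);
#'   \item the switch-off decay is fitted with two exponential modes in
#'     beta - 1 ([two_exponential_fit()]);
#'   \item the fitted decay rates, together with the just-estimated
#'     viscosity, are inverted for the two compliances through the
#'     eigenvalue sum/product relations
#'     ([compliances_from_eigenvalues()]).
#' }
#' Cycles are fitted independently; the reported coefficients are
#' across-cycle means (with standard deviations when more than one cycle is
#' available). No outlier rejection is applied.
#'
#' @param series an [interface_series()].
#' @param config a [coflow_config()]; defaults to the standard device and
#'   protocol with the program attached to the series (if any).
#' @return an object of class `"coflow_fit"` with methods `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot` and
#'   `simulate`.
#' @examples
#' truth <- ground_truth(mu_b = 2.2, C1 = 50, C2 = 1400, sigma_alpha = 0)
#' fit <- coflow_fit(simulate_measurement(truth))
#' coef(fit)
#' @export
coflow_fit <- function(series, config = NULL) {
  if (is.null(config)) {
    prog <- attr(series, "program")
    config <- if (is.null(prog)) coflow_config() else coflow_config(program = prog)
  }
  stopifnot(inherits(config, "coflow_config"))
  prog <- config$program
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  windows <- stage("select_steady_window",
                   select_steady_window(series, prog, n = config$n_steady,
                                        settle = config$settle))
  t_end <- max(series$time_s)
  per_cycle <- list()
  eigenfits <- list()
  for (i in seq_len(prog$cycles)) {
    win <- windows[windows$cycle == i, ]
    if (nrow(win) == 0) next
    a_mean <- mean(win$alpha_b); a_sd <- sd(win$alpha_b)
    mu_b <- stage("steady_viscosity",
                  as.numeric(steady_viscosity(a_mean, prog$Qr, prog$Q0,
                                              config$mu_r, config$cf)))
    t0 <- (i - 1) * prog$T_period + prog$t_on
    t_hi <- min(i * prog$T_period - prog$dt / 2, t_end)
    ef <- stage("two_exponential_fit",
                two_exponential_fit(series, t0 = t0, t_max = t_hi,
                                    min_points = config$min_points))
    cc <- stage("compliances_from_eigenvalues",
                compliances_from_eigenvalues(ef$lambda1, ef$lambda2, mu_b,
                                             config$geometry, config$mu_r,
                                             config$cf$cf0))
    eigenfits[[length(eigenfits) + 1]] <- ef
    per_cycle[[length(per_cycle) + 1]] <- data.frame(
      cycle = i, alpha_mean = a_mean, alpha_sd = a_sd, n_steady = nrow(win),
      mu_b = mu_b, d1 = ef$d1, d2 = ef$d2,
      lambda1 = ef$lambda1, lambda2 = ef$lambda2,
      C1 = cc[["C1"]], C2 = cc[["C2"]],
      rss = ef$rss, converged = ef$converged)
  }
  if (length(per_cycle) == 0) {
    stop("no complete on+off cycle could be analyzed", call. = FALSE)
  }
  pc <- do.call(rbind, per_cycle)
  est <- c(mu_b = mean(pc$mu_b), C1 = mean(pc$C1), C2 = mean(pc$C2))
  sds <- c(mu_b = sd(pc$mu_b), C1 = sd(pc$C1), C2 = sd(pc$C2))
  structure(list(
    coefficients = est, sd = sds, per_cycle = pc, eigenfits = eigenfits,
    steady = list(alpha_mean = mean(pc$alpha_mean),
                  alpha_sd = if (nrow(pc) > 1) sd(pc$alpha_mean) else
                    mean(pc$alpha_sd),
                  n = sum(pc$n_steady)),
    config = config, series = series, call = match.call()
  ), class = "coflow_fit")
}

#' @export
coef.coflow_fit <- function(object, ...) object$coefficients

#' @export
print.coflow_fit <- function(x, ...) {
  cat("Two-compliance coflow viscoelastometry fit\n")
  cat(sprintf("  cycles analyzed: %d\n", nrow(x$per_cycle)))
  cat(sprintf("  mu_b = %.4g mPa.s\n", x$coefficients[["mu_b"]]))
  cat(sprintf("  C1   = %.4g um^3/mPa (tubing + channel)\n",
              x$coefficients[["C1"]]))
  cat(sprintf("  C2   = %.4g um^3/mPa (RBC elasticity)\n",
              x$coefficients[["C2"]]))
  invisible(x)
}

#' @export
summary.coflow_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.coflow_fit")
}

#' @export
print.summary.coflow_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  steady alpha = %.4f (sd %.4f, n = %d)\n",
              f$steady$alpha_mean, f$steady$alpha_sd, f$steady$n))
  if (nrow(f$per_cycle) > 1) {
    cat(sprintf("  across-cycle sd: mu_b %.3g, C1 %.3g, C2 %.3g\n",
                f$sd[["mu_b"]], f$sd[["C1"]], f$sd[["C2"]]))
  }
  cat("\nPer-cycle estimates:\n")
  print(f$per_cycle[, c("cycle", "alpha_mean", "mu_b", "lambda1", "lambda2",
                        "C1", "C2", "converged")], row.names = FALSE)
  invisible(x)
}

#' Fitted interface trajectory
#'
#' Reconstructs the model's interface fraction at the requested times:
#' during on-phases the cycle's steady value, during off-phases the fitted
#' two-exponential decay mapped back through alpha = 1 - 1/beta. Times in
#' cycles that were not analyzed give NA.
#'
#' @param object a [coflow_fit()].
#' @param times sample times, s; defaults to the fitted series' times.
#' @param ... unused.
#' @return numeric vector of alpha values.
#' @export
predict.coflow_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$series$time_s
  prog <- object$config$program
  pc <- object$per_cycle
  out <- rep(NA_real_, length(times))
  for (r in seq_len(nrow(pc))) {
    i <- pc$cycle[r]
    t_lo <- (i - 1) * prog$T_period
    on <- times >= t_lo & times < t_lo + prog$t_on
    out[on] <- pc$alpha_mean[r]
    off <- times >= t_lo + prog$t_on & times < i * prog$T_period
    tau <- times[off] - (t_lo + prog$t_on)
    beta <- analytic_beta(tau, pc$d1[r], pc$d2[r], pc$lambda1[r], pc$lambda2[r])
    out[off] <- as.numeric(alpha_from_beta(beta))
  }
  out
}

#' @export
fitted.coflow_fit <- function(object, ...) predict(object)

#' @export
residuals.coflow_fit <- function(object, ...) {
  object$series$alpha_b - fitted(object)
}

#' @export
plot.coflow_fit <- function(x, ...) {
  s <- x$series
  plot(s$time_s, s$alpha_b, type = "p", pch = 16, cex = 0.3, col = "grey50",
       xlab = "time (s)", ylab = expression(alpha[b]), ...)
  ok <- !is.na(fitted(x))
  lines(s$time_s[ok], fitted(x)[ok], col = "firebrick", lwd = 2)
  abline(v = x$config$program$switch_times, col = "grey85", lty = 3)
  legend("topright", c("observed", "fitted"), pch = c(16, NA),
         lty = c(NA, 1), col = c("grey50", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate new experiments from a fitted model
#'
#' Draws synthetic interface series from the fitted (mu_b, C1, C2) under
#' the fit's own geometry, correction-factor model and flow program.
#'
#' @param object a [coflow_fit()].
#' @param nsim number of series.
#' @param seed RNG seed (sub-seeded per replicate).
#' @param sigma_alpha observation noise sd; default 0.005.
#' @param ... unused.
#' @return a list of [interface_series()] (length `nsim`).
#' @export
simulate.coflow_fit <- function(object, nsim = 1, seed = NULL,
                                sigma_alpha = 0.005, ...) {
  co <- coef(object)
  cfg <- object$config
  lapply(seq_len(nsim), function(k) {
    truth <- ground_truth(mu_b = co[["mu_b"]], C1 = co[["C1"]], C2 = co[["C2"]],
                          geometry = cfg$geometry, cf = cfg$cf,
                          program = cfg$program, mu_r = cfg$mu_r,
                          sigma_alpha = sigma_alpha,
                          seed = .substream_seed(seed, k))
    simulate_measurement(truth)
  })
}
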