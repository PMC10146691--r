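#' Ground truth for an in-silico experiment
#'
#' Collects everything the synthetic generator needs: the true blood
#' viscosity, the two compliances, device geometry, correction-factor
#' model, flow program, observation-noise level and seed. Condition
#' metadata (hematocrit, diluent, hardening, tubing length, ...) may be
#' attached as labels in `meta`; it does not enter the simulation.
#'
#' The default noise sd 0.005 corresponds to roughly one pixel of interface
#' quantization at the standard 150-pixel channel width.
#'
#' @param mu_b true blood viscosity, mPa.s.
#' @param C1,C2 true compliances, um^3/mPa (C1 < C2).
#' @param geometry a [channel_geometry()].
#' @param cf a [cf_model()] (defaults to the shipped model for the
#'   geometry's depth).
#' @param program a [flow_program()].
#' @param mu_r reference viscosity, mPa.s.
#' @param sigma_alpha sd of additive Gaussian observation noise on alpha.
#' @param seed global seed; per-component sub-seeds are derived from it.
#' @param meta free-form condition labels.
#' @return an object of class `"ground_truth"`.
#' @export
ground_truth <- function(mu_b = 2.2, C1 = 50, C2 = 1400,
                         geometry = channel_geometry(h = 20), cf = NULL,
                         program = flow_program(cycles = 1), mu_r = 1,
                         sigma_alpha = 0.005, seed = NULL, meta = list()) {
  if (is.null(cf)) cf <- cf_model_for_depth(geometry$h)
  .check_positive(mu_b = mu_b, C1 = C1, C2 = C2, mu_r = mu_r)
  if (C1 >= C2) stop("ground truth requires C1 < C2", call. = FALSE)
  if (sigma_alpha < 0) stop("'sigma_alpha' must be >= 0", call. = FALSE)
  structure(list(mu_b = mu_b, C1 = C1, C2 = C2, geometry = geometry,
                 cf = cf, program = program, mu_r = mu_r,
                 sigma_alpha = sigma_alpha, seed = seed, meta = meta),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: mu_b = %g mPa.s, C1 = %g, C2 = %g um^3/mPa; sigma_alpha = %g\n",
    x$mu_b, x$C1, x$C2, x$sigma_alpha))
  invisible(x)
}

#' @export
as.list.circuit_parameters <- function(x, ...) unclass(x)

# circuit parameters implied by a ground truth
.truth_params <- function(truth) {
  circuit_parameters(truth$geometry, fluid_pair(truth$mu_r, truth$mu_b),
                     C1 = truth$C1, C2 = truth$C2, CF0 = truth$cf$cf0)
}

#' Simulate a complete coflow measurement
#'
#' Generates the noiseless interface trajectory under the truth's flow
#' program and adds seeded Gaussian observation noise (clipped to
#' (0.001, 0.999)).
#'
#' Two forward engines are available. `"analytic"` (default) propagates the
#' linearized two-mode solution phase by phase with state continuity at the
#' pump switches; on-phase plateaus sit at the exact steady value of the
#' full nonlinear steady-state law, so the steady-viscosity inversion is
#' exact on noiseless data. `"nonlinear"` integrates the full
#' alpha-dependent equation with [simulate_nonlinear()] and is the oracle
#' for quantifying the linearization gap. The simulation starts from the
#' settled on-phase steady state.
#'
#' @param truth a [ground_truth()].
#' @param mode `"analytic"` or `"nonlinear"`.
#' @param images if TRUE, additionally render one synthetic frame per
#'   sample with [render_coflow_frame()] (returned in attribute
#'   `"frames"`).
#' @param image_spec options passed on to [render_coflow_frame()].
#' @return an [interface_series()] with attributes `"truth"`, `"alpha_true"`
#'   and (optionally) `"frames"`.
#' @export
simulate_measurement <- function(truth, mode = c("analytic", "nonlinear"),
                                 images = FALSE, image_spec = list()) {
  stopifnot(inherits(truth, "ground_truth"))
  mode <- match.arg(mode)
  prog <- truth$program
  params <- .truth_params(truth)
  alpha_ss <- steady_interface(truth$mu_b, prog$Q0 / prog$Qr, truth$mu_r,
                               truth$cf)

  if (mode == "nonlinear") {
    ser <- simulate_nonlinear(params, truth$cf, prog, alpha0 = alpha_ss)
    times <- ser$time_s
    alpha <- ser$alpha_b
  } else {
    lam <- eigenvalues_forward(params)
    l1 <- lam[["lambda1"]]; l2 <- lam[["lambda2"]]
    times <- program_times(prog)
    beta_on <- 1 / (1 - alpha_ss)
    bounds <- c(0, prog$switch_times)
    state <- c(beta_on, 0)  # (beta, dbeta/dt): start settled
    alpha <- numeric(length(times))
    for (i in seq_len(length(bounds) - 1)) {
      lo <- bounds[i]; hi <- bounds[i + 1]
      on <- Qb_at(prog, lo) > 0
      target <- if (on) beta_on else 1
      d <- phase_amplitudes(state[1], state[2], target, l1, l2)
      sel <- times >= lo & times < hi
      tau <- times[sel] - lo
      alpha[sel] <- as.numeric(alpha_from_beta(
        target + d[1] * exp(-l1 * tau) + d[2] * exp(-l2 * tau)))
      span <- hi - lo
      e1 <- exp(-l1 * span); e2 <- exp(-l2 * span)
      state <- c(target + d[1] * e1 + d[2] * e2,
                 -l1 * d[1] * e1 - l2 * d[2] * e2)
    }
  }

  alpha_obs <- alpha
  if (truth$sigma_alpha > 0) {
    ns <- .substream_seed(truth$seed, 1L)
    if (!is.null(ns)) set.seed(ns)
    alpha_obs <- alpha + rnorm(length(alpha), 0, truth$sigma_alpha)
  }
  alpha_obs <- pmin(pmax(alpha_obs, 0.001), 0.999)
  ser <- interface_series(times, alpha_obs, program = prog)
  attr(ser, "truth") <- truth
  attr(ser, "alpha_true") <- alpha
  if (images) {
    frames <- lapply(seq_along(alpha_obs), function(k) {
      spec <- c(list(alpha = max(min(alpha[k], 0.98), 0.02),
                     seed = .substream_seed(truth$seed %||% 0L, 1000L + k)),
                image_spec)
      do.call(render_coflow_frame, spec)
    })
    attr(ser, "frames") <- frames
  }
  ser
}

#' Parameter-recovery study over random ground truths
#'
#' Draws random truths (C1 log-uniform on 10-200, C2 log-uniform on
#' 500-5000 um^3/mPa, mu_b uniform on 1-4 mPa.s), simulates a measurement
#' at each requested noise level, runs the full inverse pipeline
#' ([coflow_fit()]) and summarizes the relative estimation error per
#' parameter and noise level. Failed fits are counted, not hidden.
#'
#' @param n_draws number of random truths.
#' @param sigma_levels noise sds to cross with the draws.
#' @param seed global seed.
#' @param program flow program for every run.
#' @param geometry device geometry.
#' @param cf correction-factor model (defaults to the geometry's shipped
#'   model).
#' @return a data.frame with one row per (sigma, parameter): columns
#'   `sigma_alpha`, `parameter`, `bias`, `rmse` (both on relative error),
#'   `n_ok`, `n_fail`; the per-run errors are in attribute `"runs"`.
#' @export
parameter_recovery_suite <- function(n_draws, sigma_levels = c(0, 0.005, 0.01),
                                     seed = 1, program = flow_program(cycles = 1),
                                     geometry = channel_geometry(h = 20),
                                     cf = NULL) {
  if (n_draws < 1) stop("'n_draws' must be at least 1", call. = FALSE)
  if (is.null(cf)) cf <- cf_model_for_depth(geometry$h)
  set.seed(.substream_seed(seed, 77L))
  draws <- data.frame(
    C1 = exp(runif(n_draws, log(10), log(200))),
    C2 = exp(runif(n_draws, log(500), log(5000))),
    mu_b = runif(n_draws, 1, 4))
  cfg <- coflow_config(geometry = geometry, program = program, cf = cf)
  runs <- list()
  for (s in seq_along(sigma_levels)) {
    for (i in seq_len(n_draws)) {
      truth <- ground_truth(mu_b = draws$mu_b[i], C1 = draws$C1[i],
                            C2 = draws$C2[i], geometry = geometry, cf = cf,
                            program = program,
                            sigma_alpha = sigma_levels[s],
                            seed = .substream_seed(seed, s * 10000L + i))
      res <- tryCatch({
        fit <- coflow_fit(simulate_measurement(truth), cfg)
        co <- coef(fit)
        data.frame(sigma_alpha = sigma_levels[s], draw = i, ok = TRUE,
                   err_mu_b = co[["mu_b"]] / truth$mu_b - 1,
                   err_C1 = co[["C1"]] / truth$C1 - 1,
                   err_C2 = co[["C2"]] / truth$C2 - 1)
      }, error = function(e) {
        data.frame(sigma_alpha = sigma_levels[s], draw = i, ok = FALSE,
                   err_mu_b = NA_real_, err_C1 = NA_real_, err_C2 = NA_real_)
      })
      runs[[length(runs) + 1]] <- res
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$sigma_alpha), function(g) {
    do.call(rbind, lapply(c("mu_b", "C1", "C2"), function(p) {
      e <- g[[paste0("err_", p)]][g$ok]
      data.frame(sigma_alpha = g$sigma_alpha[1], parameter = p,
                 bias = mean(e), rmse = sqrt(mean(e^2)),
                 n_ok = sum(g$ok), n_fail = sum(!g$ok))
    }))
  }))
  rownames(summ) <- NULL
  attr(summ, "runs") <- runs
  summ
}
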