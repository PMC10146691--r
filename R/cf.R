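#' Correction-factor model CF(alpha)
#'
#' The two-resistor virtual-wall idealization of the coflowing channel is
#' corrected by an empirical multiplier CF(alpha) on the blood-stream
#' conductance, calibrated against fluids of known viscosity. The model is a
#' polynomial in the interface fraction with a validity range and a scalar
#' interface-averaged constant `cf0` used to linearize the governing
#' equation.
#'
#' @param coefficients numeric vector of polynomial coefficients in
#'   ascending degree (intercept first); degree at most 5.
#' @param depth channel depth the calibration applies to, um (NA if generic).
#' @param range validity range of alpha, default `c(0.1, 0.9)`.
#' @param cf0 interface-averaged constant; computed with [cf0_constant()]
#'   on the default grid when omitted.
#' @param r_squared optional calibration R^2 (diagnostic).
#' @return an object of class `"cf_model"`.
#' @seealso [builtin_cf_models()], [fit_cf_polynomial()]
#' @export
cf_model <- function(coefficients, depth = NA_real_, range = c(0.1, 0.9),
                     cf0 = NULL, r_squared = NA_real_) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1 || length(coefficients) > 6) {
    stop("polynomial degree must be between 0 and 5", call. = FALSE)
  }
  stopifnot(length(range) == 2, range[1] < range[2],
            range[1] > 0, range[2] < 1)
  m <- structure(list(coefficients = coefficients, depth = depth,
                      range = range, cf0 = NA_real_, r_squared = r_squared),
                 class = "cf_model")
  grid <- seq(range[1], range[2], by = 0.01)
  if (any(cf_eval(m, grid) <= 0)) {
    stop("CF(alpha) must be positive over the validity range", call. = FALSE)
  }
  m$cf0 <- if (is.null(cf0)) cf0_constant(m) else as.numeric(cf0)
  .check_positive(cf0 = m$cf0)
  m
}

#' Constant correction-factor model
#'
#' @param value the constant CF value (also its cf0).
#' @param range validity range of alpha.
#' @return a degree-0 [cf_model()].
#' @export
cf_constant <- function(value, range = c(0.1, 0.9)) {
  cf_model(value, range = range, cf0 = value)
}

#' Evaluate CF(alpha)
#'
#' @param model a [cf_model()].
#' @param alpha interface fractions.
#' @param deriv 0 for CF(alpha), 1 for its first derivative.
#' @return numeric vector.
#' @export
cf_eval <- function(model, alpha, deriv = 0) {
  stopifnot(inherits(model, "cf_model"))
  co <- model$coefficients
  if (deriv == 1) {
    if (length(co) == 1) return(rep(0, length(alpha)))
    co <- co[-1] * seq_along(co[-1])
  } else if (deriv != 0) {
    stop("'deriv' must be 0 or 1", call. = FALSE)
  }
  # Horner evaluation
  out <- rep(co[length(co)], length(alpha))
  if (length(co) > 1) {
    for (i in (length(co) - 1):1) out <- out * alpha + co[i]
  }
  out
}

#' @export
predict.cf_model <- function(object, alpha, ...) cf_eval(object, alpha)

#' @export
print.cf_model <- function(x, ...) {
  deg <- length(x$coefficients) - 1
  terms <- sprintf("%.6g*a^%d", x$coefficients, 0:deg)
  cat(sprintf("Correction-factor model%s, degree %d:\n",
              if (is.na(x$depth)) "" else sprintf(" (h = %g um)", x$depth), deg))
  cat("  CF(a) =", paste(terms, collapse = " + "), "\n")
  cat(sprintf("  validity: alpha in [%g, %g]; CF0 = %.4g", x$range[1], x$range[2], x$cf0))
  if (!is.na(x$r_squared)) cat(sprintf("; R^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Pointwise correction factor from a calibration observation
#'
#' With a test fluid of known viscosity, the measured interface fraction
#' determines the correction factor through the inverted steady-state law:
#' `CF = (mu_t/mu_r) * ((1 - alpha_t)/alpha_t) * (Q_t/Q_r)`.
#'
#' @param alpha_t measured interface fraction of the test stream.
#' @param mu_t,mu_r test/reference viscosities, mPa.s.
#' @param Q_t,Q_r test/reference flow rates (any common unit).
#' @return the correction factor (dimensionless).
#' @examples
#' cf_point(0.75, mu_t = 3, mu_r = 1) # 1
#' @export
cf_point <- function(alpha_t, mu_t, mu_r, Q_t = 1, Q_r = 1) {
  .check_positive(mu_t = mu_t, mu_r = mu_r, Q_t = Q_t, Q_r = Q_r)
  if (any(!is.finite(alpha_t)) || any(alpha_t <= 0) || any(alpha_t >= 1)) {
    stop("degenerate observation: 'alpha_t' must lie strictly in (0, 1)",
         call. = FALSE)
  }
  (mu_t / mu_r) * ((1 - alpha_t) / alpha_t) * (Q_t / Q_r)
}

#' Fit a polynomial correction-factor model to calibration points
#'
#' Ordinary least squares of CF on powers of alpha. The default degree
#' follows the shipped per-depth calibrations (3 for h = 4 um, 2 for
#' h = 10 um, 5 for h = 20 um); pass `degree` explicitly otherwise.
#'
#' @param alpha interface fractions of the calibration observations.
#' @param cf correction factors (e.g. from [cf_point()]).
#' @param degree polynomial degree (<= 5).
#' @param depth channel depth label, um; also selects the default degree.
#' @param range validity range stored on the returned model.
#' @return a [cf_model()] with `r_squared` and coefficient standard errors
#'   (attribute `"se"`) attached.
#' @export
fit_cf_polynomial <- function(alpha, cf, degree = NULL, depth = NA_real_,
                              range = c(0.1, 0.9)) {
  stopifnot(length(alpha) == length(cf))
  if (is.null(degree)) {
    degree <- switch(as.character(depth), "4" = 3, "10" = 2, "20" = 5,
                     stop("no default degree for this depth; supply 'degree'",
                          call. = FALSE))
  }
  if (degree > 5) stop("polynomial degree must be at most 5", call. = FALSE)
  if (length(alpha) < degree + 1) {
    stop(sprintf("need at least %d points to fit degree %d", degree + 1, degree),
         call. = FALSE)
  }
  X <- outer(alpha, 0:degree, `^`)
  colnames(X) <- paste0("a", 0:degree)
  qrX <- qr(X)
  if (qrX$rank < degree + 1) {
    stop("calibration design is rank deficient (alpha values too clustered)",
         call. = FALSE)
  }
  fit <- lm(cf ~ X - 1)
  co <- unname(coef(fit))
  # noiseless calibrations fit perfectly; the se's are then zero/NaN
  s <- suppressWarnings(summary(fit))
  m <- cf_model(co, depth = depth, range = range,
                r_squared = if (length(cf) > degree + 1) {
                  1 - sum(resid(fit)^2) / sum((cf - mean(cf))^2)
                } else 1)
  attr(m, "se") <- unname(s$coefficients[, "Std. Error"])
  m
}

#' Interface-averaged constant correction factor CF0
#'
#' Replacing CF(alpha) by a constant linearizes the governing equation.
#' The constant is chosen so that the nonlinear term alpha*CF(alpha)/(1-alpha)
#' is matched on average: CF0 is the mean of CF over a grid of interface
#' values, weighted by alpha/(1-alpha).
#'
#' @param model a [cf_model()].
#' @param alpha_grid grid of interface values; defaults to a uniform grid
#'   over the model's validity range, step 0.01.
#' @return the scalar CF0.
#' @export
cf0_constant <- function(model, alpha_grid = NULL) {
  stopifnot(inherits(model, "cf_model"))
  if (is.null(alpha_grid)) {
    alpha_grid <- seq(model$range[1], model$range[2], by = 0.01)
  }
  if (length(alpha_grid) == 0) stop("empty alpha grid", call. = FALSE)
  if (any(alpha_grid <= 0) || any(alpha_grid >= 1)) {
    stop("alpha grid must lie strictly in (0, 1)", call. = FALSE)
  }
  w <- alpha_grid / (1 - alpha_grid)
  sum(cf_eval(model, alpha_grid) * w) / sum(w)
}

# printed per-depth calibrations; CF0 values are the published constants,
# kept as authoritative (the averaging set behind them is not recoverable)
.BUILTIN_CF <- list(
  "4"  = list(coef = c(-0.1289, 4.1983, -7.669, 7.5698), cf0 = 1.637,
              r2 = 0.9858),
  "10" = list(coef = c(0.38, 0.9378, 0.6931), cf0 = 1.41, r2 = 0.9525),
  "20" = list(coef = c(0.4163, 2.5117, -11.062, 36.954, -54.452, 27.95),
              cf0 = 1.183, r2 = 0.9354)
)

#' Shipped correction-factor calibrations
#'
#' Returns the per-depth polynomial calibrations (glycerin 30% vs 1x PBS)
#' for channel depths 4, 10 and 20 um, with their published CF0 constants.
#' [cf0_constant()] can recompute an average from any grid but never
#' overrides these shipped values.
#'
#' @return named list of [cf_model()] objects keyed by depth ("4", "10", "20").
#' @examples
#' builtin_cf_models()[["20"]]
#' @export
builtin_cf_models <- function() {
  out <- lapply(names(.BUILTIN_CF), function(d) {
    b <- .BUILTIN_CF[[d]]
    cf_model(b$coef, depth = as.numeric(d), cf0 = b$cf0, r_squared = b$r2)
  })
  names(out) <- names(.BUILTIN_CF)
  out
}

#' Look up the shipped calibration for one channel depth
#'
#' @param depth channel depth, um (4, 10 or 20).
#' @return a [cf_model()].
#' @export
cf_model_for_depth <- function(depth) {
  key <- as.character(depth)
  if (!key %in% names(.BUILTIN_CF)) {
    stop(sprintf("no shipped correction-factor model for depth %s um (have: %s)",
                 key, paste(names(.BUILTIN_CF), collapse = ", ")), call. = FALSE)
  }
  builtin_cf_models()[[key]]
}

#' Read/write a correction-factor model as JSON
#'
#' @param model a [cf_model()].
#' @param path file path.
#' @return `read_cf_model` returns a [cf_model()]; `write_cf_model` the path,
#'   invisibly.
#' @export
write_cf_model <- function(model, path) {
  stopifnot(inherits(model, "cf_model"))
  jsonlite::write_json(
    list(depth = model$depth, coefficients = model$coefficients,
         range = model$range, cf0 = model$cf0, r_squared = model$r_squared),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_cf_model
#' @export
read_cf_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf_model(x$coefficients, depth = if (is.null(x$depth)) NA_real_ else x$depth,
           range = x$range, cf0 = x$cf0,
           r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared)
}
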