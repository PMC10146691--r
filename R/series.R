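#' Periodic on/off flow program
#'
#' The blood pump runs a square wave: amplitude `Q0` for the first
#' `on_fraction` of each period, zero for the rest; the reference pump runs
#' constant `Qr`. The default protocol is Q0 = Qr = 1 mL/h, period
#' T = 240 s (120 s on / 120 s off), sampled every 0.5 s.
#'
#' @param Q0 pump amplitude, mL/h.
#' @param T_period period of the on/off pattern, s.
#' @param cycles number of full periods.
#' @param dt sampling interval, s (must be at most T/4).
#' @param on_fraction fraction of the period with the blood pump on.
#' @param Qr reference-fluid flow rate, mL/h.
#' @return an object of class `"flow_program"`.
#' @examples
#' flow_program(cycles = 2)
#' @export
flow_program <- function(Q0 = 1, T_period = 240, cycles = 1, dt = 0.5,
                         on_fraction = 0.5, Qr = 1) {
  .check_positive(Q0 = Q0, T_period = T_period, dt = dt, Qr = Qr)
  if (!is.numeric(cycles) || cycles < 1) {
    stop("'cycles' must be at least 1", call. = FALSE)
  }
  if (on_fraction <= 0 || on_fraction >= 1) {
    stop("'on_fraction' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (dt > T_period / 4) {
    stop("sampling interval 'dt' must be at most T/4 to resolve the phases",
         call. = FALSE)
  }
  cycles <- as.integer(cycles)
  t_on <- T_period * on_fraction
  # phase boundaries: on->off at i*T + t_on, off->on at (i+1)*T
  switches <- sort(c((0:(cycles - 1)) * T_period + t_on, (1:cycles) * T_period))
  structure(list(Q0 = Q0, T_period = T_period, cycles = cycles, dt = dt,
                 on_fraction = on_fraction, Qr = Qr, t_on = t_on,
                 switch_times = switches),
            class = "flow_program")
}

#' @export
print.flow_program <- function(x, ...) {
  cat(sprintf("Flow program: Q0 = %g mL/h on/off (T = %g s, %.0f%% on), Qr = %g mL/h\n",
              x$Q0, x$T_period, 100 * x$on_fraction, x$Qr))
  cat(sprintf("  %d cycle(s), dt = %g s, %d samples\n",
              x$cycles, x$dt, length(program_times(x))))
  invisible(x)
}

#' Sample times and blood flow of a program
#'
#' `program_times` gives the sampling grid (half-open: t = 0 up to but not
#' including cycles*T). `Qb_at` gives the blood flow rate at arbitrary
#' times; the pump is on for `t mod T` in `[0, T*on_fraction)`.
#'
#' @param program a [flow_program()].
#' @param t times, s.
#' @return times in s, or flow rates in mL/h.
#' @export
program_times <- function(program) {
  seq(0, program$cycles * program$T_period - program$dt, by = program$dt)
}

#' @rdname program_times
#' @export
Qb_at <- function(program, t) {
  phase <- t %% program$T_period
  ifelse(phase < program$t_on & t < program$cycles * program$T_period,
         program$Q0, 0)
}

#' Interface time series
#'
#' Timestamped interface-fraction samples, the method's central observable.
#' Times must be strictly increasing and every alpha strictly inside (0, 1);
#' samples outside the model validity range (0.1, 0.9) are kept but flagged
#' in the `valid` column.
#'
#' @param times sample times, s.
#' @param alpha interface fractions.
#' @param program optional [flow_program()]; adds a `phase` column
#'   ("on"/"off").
#' @return an object of class `"interface_series"` (also a data.frame with
#'   columns `time_s`, `alpha_b`, optionally `phase`, and `valid`).
#' @export
interface_series <- function(times, alpha, program = NULL) {
  stopifnot(length(times) == length(alpha))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("all 'alpha' must lie strictly in (0, 1)", call. = FALSE)
  }
  df <- data.frame(time_s = as.numeric(times), alpha_b = as.numeric(alpha))
  if (!is.null(program)) {
    stopifnot(inherits(program, "flow_program"))
    df$phase <- ifelse(Qb_at(program, df$time_s) > 0, "on", "off")
  }
  df$valid <- alpha > 0.1 & alpha < 0.9
  structure(df, class = c("interface_series", "data.frame"), program = program)
}

#' @export
print.interface_series <- function(x, ...) {
  cat(sprintf("Interface series: %d samples over [%g, %g] s; alpha in [%.3f, %.3f]",
              nrow(x), min(x$time_s), max(x$time_s),
              min(x$alpha_b), max(x$alpha_b)))
  nbad <- sum(!x$valid)
  if (nbad > 0) cat(sprintf(" (%d outside validity range)", nbad))
  cat("\n")
  invisible(x)
}

#' @export
plot.interface_series <- function(x, ..., xlab = "time (s)",
                                  ylab = expression(alpha[b]), type = "l") {
  plot(x$time_s, x$alpha_b, xlab = xlab, ylab = ylab, type = type, ...)
  prog <- attr(x, "program")
  if (!is.null(prog)) abline(v = prog$switch_times, col = "grey80", lty = 3)
  invisible(x)
}

#' Reciprocal interface coordinate of a series
#'
#' @param series an [interface_series()].
#' @return numeric vector beta = 1/(1 - alpha).
#' @export
beta_of <- function(series) 1 / (1 - series$alpha_b)

#' Read and write interface series as CSV
#'
#' The on-disk format is a CSV with header `time_s,alpha_b` and an optional
#' `phase` column; floats are written at full precision so that a
#' write/read roundtrip is lossless.
#'
#' @param series an [interface_series()].
#' @param path file path.
#' @param program optional [flow_program()] to re-attach on read.
#' @return `read_series` returns an [interface_series()]; `write_series`
#'   the path, invisibly.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)
  df$valid <- NULL
  df$time_s <- sprintf("%.17g", df$time_s)
  df$alpha_b <- sprintf("%.17g", df$alpha_b)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, program = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "alpha_b")
  if (!all(need %in% names(df))) {
    stop("series CSV must have columns time_s,alpha_b", call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(interface_series(numeric(0), numeric(0), program = program))
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$alpha_b))
  if (length(bad) > 0) {
    stop(sprintf("malformed series rows (after header): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0)) {
    stop(sprintf("non-monotone times at row(s) %s",
                 paste(which(diff(df$time_s) <= 0) + 1, collapse = ", ")),
         call. = FALSE)
  }
  interface_series(df$time_s, df$alpha_b, program = program)
}
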