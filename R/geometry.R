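#' Channel geometry of the coflow device
#'
#' Describes the three-channel microfluidic device: a blood channel of length
#' `l1`, a coflowing channel of length `l2`, both of width `w` and depth `h`.
#' Tubing lengths are carried as metadata only (they influence the fitted
#' compliances physically but do not enter the circuit equations).
#'
#' The lumped two-dimensional flow approximation requires a shallow channel;
#' a warning is issued when the aspect ratio h/w is not below 0.1.
#'
#' @param l1 blood-channel length, um.
#' @param l2 coflowing-channel length, um.
#' @param w channel width, um.
#' @param h channel depth, um.
#' @param L_in,L_out inlet/outlet tubing lengths, mm (metadata).
#' @return an object of class `"channel_geometry"`.
#' @examples
#' channel_geometry(h = 20)
#' @export
channel_geometry <- function(l1 = 7500, l2 = 4800, w = 250, h = 20,
                             L_in = 300, L_out = 300) {
  .check_positive(l1 = l1, l2 = l2, w = w, h = h, L_in = L_in, L_out = L_out)
  if (h / w >= 0.1) {
    warning(sprintf(
      "aspect ratio h/w = %.3f >= 0.1: the 2D shallow-channel approximation may not hold",
      h / w), call. = FALSE)
  }
  structure(list(l1 = l1, l2 = l2, w = w, h = h, L_in = L_in, L_out = L_out),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("Coflow channel geometry (um):\n")
  cat(sprintf("  blood channel l1 = %g, coflowing channel l2 = %g\n", x$l1, x$l2))
  cat(sprintf("  width w = %g, depth h = %g (aspect ratio %.3f)\n", x$w, x$h, x$h / x$w))
  cat(sprintf("  tubing: L_in = %g mm, L_out = %g mm\n", x$L_in, x$L_out))
  invisible(x)
}

#' Viscosities of the reference and test fluids
#'
#' @param mu_r reference-fluid viscosity, mPa.s.
#' @param mu_b test-fluid (blood) viscosity, mPa.s.
#' @return an object of class `"fluid_pair"`.
#' @export
fluid_pair <- function(mu_r = 1, mu_b) {
  .check_positive(mu_r = mu_r, mu_b = mu_b)
  structure(list(mu_r = mu_r, mu_b = mu_b), class = "fluid_pair")
}

#' @export
print.fluid_pair <- function(x, ...) {
  cat(sprintf("Fluid pair: mu_r = %g mPa.s (reference), mu_b = %g mPa.s (test)\n",
              x$mu_r, x$mu_b))
  invisible(x)
}

#' Hydraulic resistance of a shallow rectangular channel
#'
#' Planar Poiseuille resistance `12 * mu * l / (w * h^3)` of a channel
#' segment, valid for depth much smaller than width.
#'
#' @param mu fluid viscosity, mPa.s.
#' @param l segment length, um.
#' @param w channel width, um.
#' @param h channel depth, um.
#' @return resistance in mPa.s/um^3.
#' @examples
#' rect_resistance(mu = 1, l = 4800, w = 250, h = 20) # 0.0288
#' @export
rect_resistance <- function(mu, l, w, h) {
  .check_positive(mu = mu, l = l, w = w, h = h)
  12 * mu * l / (w * h^3)
}

#' Resistances of the two coflowing streams
#'
#' The interface is treated as a virtual wall splitting the coflowing
#' channel into a reference stream of width `(1 - alpha) * w` and a blood
#' stream of width `alpha * w`; the blood-stream resistance carries the
#' empirical correction factor for the virtual-wall idealization.
#'
#' @param alpha interface fraction (blood-filled width / channel width).
#' @param geom a [channel_geometry()].
#' @param fluids a [fluid_pair()].
#' @param cf correction factor CF evaluated at `alpha`.
#' @return named numeric vector `c(R_r2, R_b2)` in mPa.s/um^3.
#' @export
stream_resistances <- function(alpha, geom, fluids, cf) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(fluids, "fluid_pair"))
  .check_positive(cf = cf)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("degenerate stream: 'alpha' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0.1 || alpha >= 0.9) {
    warning("alpha outside the model validity range (0.1, 0.9)", call. = FALSE)
  }
  base <- 12 * geom$l2 / (geom$w * geom$h^3)
  c(R_r2 = fluids$mu_r * base / (1 - alpha),
    R_b2 = fluids$mu_b * base / (cf * alpha))
}

#' Wall shear rate in the blood channel
#'
#' Plane-Poiseuille wall shear rate `6 * Q_b / (w * h^2)` using the full
#' channel width. Note that published shear-rate ranges for this protocol
#' are larger than this formula yields with the full width; the effective
#' width behind those figures is not recoverable, so this helper implements
#' the formula as printed and leaves the choice of width to the caller.
#'
#' @param Q_b blood flow rate, mL/h.
#' @param w channel width, um.
#' @param h channel depth, um.
#' @return shear rate in 1/s.
#' @examples
#' shear_rate(1, w = 250, h = 20) # about 16667 1/s
#' @export
shear_rate <- function(Q_b, w, h) {
  .check_positive(Q_b = Q_b, w = w, h = h)
  6 * ml_h_to_um3_s(Q_b) / (w * h^2)
}
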