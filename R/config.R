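#' Experiment configuration
#'
#' Bundles everything an analysis or simulation run needs: channel
#' geometry, reference viscosity, flow program, correction-factor model and
#' fit options. Field units are explicit in the on-disk names
#' (`Q0_mL_h`, `T_s`, `dt_s`, ...).
#'
#' @param geometry a [channel_geometry()].
#' @param mu_r reference viscosity, mPa.s.
#' @param mu_b optional known blood viscosity, mPa.s (used by simulation;
#'   estimated by the fit otherwise).
#' @param program a [flow_program()].
#' @param cf a [cf_model()], or a channel depth (4/10/20) selecting the
#'   shipped calibration.
#' @param n_steady steady-window length, samples.
#' @param settle settling time after switch-on, s.
#' @param min_points minimum off-phase samples for the transient fit.
#' @return an object of class `"coflow_config"`.
#' @export
coflow_config <- function(geometry = channel_geometry(), mu_r = 1,
                          mu_b = NULL, program = flow_program(),
                          cf = geometry$h, n_steady = 50, settle = 70,
                          min_points = 40) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(program, "flow_program"))
  if (!inherits(cf, "cf_model")) cf <- cf_model_for_depth(cf)
  .check_positive(mu_r = mu_r, n_steady = n_steady, settle = settle,
                  min_points = min_points)
  if (!is.null(mu_b)) .check_positive(mu_b = mu_b)
  structure(list(geometry = geometry, mu_r = mu_r, mu_b = mu_b,
                 program = program, cf = cf, n_steady = n_steady,
                 settle = settle, min_points = min_points),
            class = "coflow_config")
}

#' @export
print.coflow_config <- function(x, ...) {
  cat("Coflow run configuration\n")
  print(x$geometry); print(x$program)
  cat(sprintf("  mu_r = %g mPa.s%s; CF model depth %s (CF0 = %.4g)\n",
              x$mu_r,
              if (is.null(x$mu_b)) "" else sprintf(", mu_b = %g mPa.s", x$mu_b),
              x$cf$depth, x$cf$cf0))
  cat(sprintf("  steady window: last %d samples, settle %g s\n",
              x$n_steady, x$settle))
  invisible(x)
}

#' Load a configuration file (YAML or JSON)
#'
#' Recognized sections: `geometry` (l1, l2, w, h, L_in, L_out, um),
#' `fluids` (mu_r, mu_b, mPa.s), `program` (Q0_mL_h, Qr_mL_h, T_s, cycles,
#' dt_s, on_fraction), `cf` (depth, or coefficients/cf0/range), `fit`
#' (n_steady, settle, min_points). Missing fields take the default device
#' protocol (l1 = 7500, l2 = 4800, w = 250 um; Q0 = Qr = 1 mL/h; T = 240 s;
#' dt = 0.5 s). Unknown keys produce a warning, not an error; invalid
#' values produce itemized errors.
#'
#' @param path config file path (.yaml/.yml/.json).
#' @return a [coflow_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("geometry", "fluids", "program", "cf", "fit", "h")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  # bare {h: 20} shorthand
  geo <- raw$geometry %||% list()
  if (!is.null(raw$h)) geo$h <- raw$h
  take <- function(lst, nm, default) if (is.null(lst[[nm]])) default else lst[[nm]]
  geometry <- channel_geometry(
    l1 = take(geo, "l1", 7500), l2 = take(geo, "l2", 4800),
    w = take(geo, "w", 250), h = take(geo, "h", 20),
    L_in = take(geo, "L_in", 300), L_out = take(geo, "L_out", 300))
  prog <- raw$program %||% list()
  program <- flow_program(
    Q0 = take(prog, "Q0_mL_h", 1), T_period = take(prog, "T_s", 240),
    cycles = take(prog, "cycles", 1), dt = take(prog, "dt_s", 0.5),
    on_fraction = take(prog, "on_fraction", 0.5),
    Qr = take(prog, "Qr_mL_h", 1))
  cfspec <- raw$cf %||% list()
  cf <- if (!is.null(cfspec$coefficients)) {
    cf_model(unlist(cfspec$coefficients),
             depth = take(cfspec, "depth", NA_real_),
             range = unlist(take(cfspec, "range", c(0.1, 0.9))),
             cf0 = cfspec$cf0)
  } else {
    cf_model_for_depth(take(cfspec, "depth", geometry$h))
  }
  fl <- raw$fluids %||% list()
  fit <- raw$fit %||% list()
  coflow_config(geometry = geometry, mu_r = take(fl, "mu_r", 1),
                mu_b = fl$mu_b, program = program, cf = cf,
                n_steady = take(fit, "n_steady", 50),
                settle = take(fit, "settle", 70),
                min_points = take(fit, "min_points", 40))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit result as JSON
#'
#' Serializes all fields of a fitted [coflow_fit()] object (aggregate and
#' per-cycle estimates, transient-fit diagnostics) plus provenance: the
#' package version and an MD5 hash of the configuration.
#'
#' @param fit a [coflow_fit()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result <- function(fit, path) {
  stopifnot(inherits(fit, "coflow_fit"))
  cfg_json <- jsonlite::toJSON(unclass_deep(fit$config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  out <- list(
    estimates = as.list(coef(fit)),
    sd = as.list(fit$sd),
    per_cycle = fit$per_cycle,
    steady = fit$steady,
    provenance = list(
      package = "coflow",
      version = as.character(packageVersion("coflow")),
      config_md5 = hash,
      config = unclass_deep(fit$config))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

# strip S3 classes recursively so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
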