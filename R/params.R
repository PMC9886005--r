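#' Physical-unit LIF neuron parameters
#'
#' Bundles the parameters of a leaky integrate-and-fire point neuron in the
#' physical units used by electrophysiology databases: capacitance in pF,
#' time constants in ms, potentials in mV, currents in pA. The derived
#' membrane resistance is `R = tau_v / c_m` (GOhm, since ms/pF = GOhm).
#'
#' @param c_m Membrane capacitance (pF). Must be positive.
#' @param tau_v Membrane time constant (ms). Must be positive.
#' @param e_l Resting potential (mV).
#' @param v_r Reset potential (mV). Must satisfy `theta > v_r`.
#' @param theta Firing threshold (mV).
#' @param i_bias Constant bias current (pA). Default 0.
#' @param tau_syn Synaptic current time constant (ms). Default 5.
#' @param w_syn Synaptic weight amplitude (pA jump in synaptic current per
#'   afferent spike). If `NULL` (default) it is chosen with [psp_weight()]
#'   so that a single spike produces a peak subthreshold deflection of
#'   about 1 mV.
#'
#' @return An object of class `lif_params`.
#' @seealso [mapping_config()], [map_neuron()], [psp_weight()]
#' @export
#' @examples
#' p <- lif_params(c_m = 170.21, tau_v = 25, e_l = -70, v_r = -70,
#'                 theta = -43, i_bias = 200)
#' p$r_m  # membrane resistance, GOhm
lif_params <- function(c_m, tau_v, e_l, v_r, theta, i_bias = 0,
                       tau_syn = 5, w_syn = NULL) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  c_m <- num1(c_m, "c_m"); tau_v <- num1(tau_v, "tau_v")
  e_l <- num1(e_l, "e_l"); v_r <- num1(v_r, "v_r")
  theta <- num1(theta, "theta"); i_bias <- num1(i_bias, "i_bias")
  tau_syn <- num1(tau_syn, "tau_syn")
  if (c_m <= 0) stop("capacitance 'c_m' must be positive", call. = FALSE)
  if (tau_v <= 0) stop("time constant 'tau_v' must be positive", call. = FALSE)
  if (tau_syn <= 0) stop("time constant 'tau_syn' must be positive", call. = FALSE)
  if (theta <= v_r)
    stop("threshold 'theta' must exceed reset 'v_r' (reset must be subthreshold)",
         call. = FALSE)
  p <- structure(
    list(c_m = c_m, tau_v = tau_v, e_l = e_l, v_r = v_r, theta = theta,
         i_bias = i_bias, tau_syn = tau_syn, w_syn = NA_real_,
         r_m = tau_v / c_m),
    class = "lif_params")
  p$w_syn <- if (is.null(w_syn)) psp_weight(p) else num1(w_syn, "w_syn")
  p
}

#' Synaptic weight giving a target peak PSP amplitude
#'
#' For an exponential postsynaptic current of time constant `tau_syn`
#' feeding a membrane with time constant `tau_v`, the peak voltage
#' deflection caused by a single spike of weight `w` (pA) is
#' `w/c_m * (exp(-t*/tau_syn) - exp(-t*/tau_v)) / (1/tau_v - 1/tau_syn)`
#' at the peak time `t* = log(tau_v/tau_syn) / (1/tau_syn - 1/tau_v)`.
#' This returns the `w` that makes the peak equal `peak_mv`.
#'
#' @param params A [lif_params()] object.
#' @param peak_mv Desired peak deflection (mV). Default 1.
#' @return Synaptic weight (pA).
#' @export
psp_weight <- function(params, peak_mv = 1) {
  tv <- params$tau_v; ts <- params$tau_syn
  if (tv == ts) {
    # alpha-function limit: peak of (t/tau) exp(1 - t/tau) is at t = tau
    amp <- ts * exp(-1)
  } else {
    tstar <- log(tv / ts) / (1 / ts - 1 / tv)
    amp <- (exp(-tstar / ts) - exp(-tstar / tv)) / (1 / tv - 1 / ts)
  }
  peak_mv * params$c_m / amp
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF neuron parameters (physical units)\n")
  cat(sprintf("  c_m     %8.2f pF      tau_v   %6.2f ms\n", x$c_m, x$tau_v))
  cat(sprintf("  e_l     %8.2f mV      v_r     %6.2f mV\n", x$e_l, x$v_r))
  cat(sprintf("  theta   %8.2f mV      i_bias  %6.2f pA\n", x$theta, x$i_bias))
  cat(sprintf("  tau_syn %8.2f ms      w_syn   %6.2f pA\n", x$tau_syn, x$w_syn))
  cat(sprintf("  derived r_m = tau_v/c_m = %.4f GOhm\n", x$r_m))
  invisible(x)
}

#' Precision configuration for the hardware mapping
#'
#' The two free precision knobs of the mapping: `v_s`, the voltage scale in
#' mV per hardware level (smaller = finer voltage resolution), and `dt`,
#' the physical duration in ms represented by one hardware time step
#' (smaller = finer temporal resolution).
#'
#' @param v_s Voltage scale (mV per level). Default `1e-4` (10,000 levels
#'   per mV).
#' @param dt Temporal scale (ms per step). Default 1.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(v_s = 1e-4, dt = 1) {
  if (!is.numeric(v_s) || length(v_s) != 1L || !is.finite(v_s) || v_s <= 0)
    stop("'v_s' must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  structure(list(v_s = as.numeric(v_s), dt = as.numeric(dt)),
            class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat(sprintf("mapping config: v_s = %g mV/level (%g levels/mV), dt = %g ms/step\n",
              x$v_s, 1 / x$v_s, x$dt))
  invisible(x)
}

#' Worked example neuron parameter sets
#'
#' The two mouse-visual-cortex LIF parameter sets used throughout the
#' worked single-neuron examples: set 1 is driven by a 200 pA bias current
#' (tau_v = 25 ms, c_m = 170.21 pF), set 2 by external spike trains
#' (tau_v = 22 ms, c_m = 170 pF, zero bias). Both have resting and reset
#' potential -70 mV and threshold -43 mV.
#'
#' @param set Which set, 1 or 2.
#' @param ... Overrides passed on to [lif_params()] (e.g. `tau_syn`).
#' @return A [lif_params()] object.
#' @export
example_neuron <- function(set = 1, ...) {
  args <- switch(as.character(set),
    "1" = list(c_m = 170.21, tau_v = 25, e_l = -70, v_r = -70,
               theta = -43, i_bias = 200),
    "2" = list(c_m = 170.0, tau_v = 22, e_l = -70, v_r = -70,
               theta = -43, i_bias = 0),
    stop("'set' must be 1 or 2", call. = FALSE))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(lif_params, args)
}

#' Read / write neuron parameter tables
#'
#' CSV (or JSON) files with one row (or record) per neuron and columns named
#' after the [lif_params()] fields: `c_m, tau_v, e_l, v_r, theta, i_bias,
#' tau_syn, w_syn` (the last three optional). Units are ms, mV, pA, pF.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `read_lif_params()` returns a list of `lif_params` objects.
#' @export
read_lif_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  if ("delta_v" %in% names(df))
    stop("file appears to contain already-mapped hardware parameters, ",
         "not physical-unit neuron parameters", call. = FALSE)
  req <- c("c_m", "tau_v", "e_l", "v_r", "theta")
  if (!all(req %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(names(df),
      c(req, "i_bias", "tau_syn", "w_syn")), drop = TRUE])
    do.call(lif_params, args)
  })
}

#' @param params A `lif_params` object or list of them.
#' @rdname read_lif_params
#' @export
write_lif_params <- function(params, path) {
  if (inherits(params, "lif_params")) params <- list(params)
  df <- do.call(rbind, lapply(params, function(p)
    data.frame(c_m = p$c_m, tau_v = p$tau_v, e_l = p$e_l, v_r = p$v_r,
               theta = p$theta, i_bias = p$i_bias, tau_syn = p$tau_syn,
               w_syn = p$w_syn)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
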