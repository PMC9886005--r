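#' Pair a reference trace with an inverse-mapped emulator trace
#'
#' Inverse-maps the emulator's integer states back to physical units
#' (`V = v * v_s + v_r` for the voltage; `I = u * c_m * v_s / dt` for the
#' current) and samples the reference trace at the emulator's step times.
#' The initial state (step 0) is excluded, so a 500 ms run at
#' `dt = 1` pairs 500 samples.
#'
#' @param ref A `lif_trace` from [run_reference()].
#' @param emu An `emulator_trace` from [run_emulator()].
#' @param which Compare the membrane potential (`"v"`, default) or the
#'   synaptic current (`"u"`).
#' @return An object of class `paired_series`: list with `y_l`
#'   (inverse-mapped emulator values), `y_b` (reference values), `n`, and
#'   the time base `times` (ms).
#' @export
align_traces <- function(ref, emu, which = c("v", "u")) {
  stopifnot(inherits(ref, "lif_trace"), inherits(emu, "emulator_trace"))
  which <- match.arg(which)
  cfg <- emu$config
  dt <- cfg$cfg$dt
  dur_emu <- emu$n_steps * dt
  if (abs(dur_emu - ref$duration) > 1e-9)
    stop(sprintf("incompatible durations: reference %g ms vs emulator %g ms",
                 ref$duration, dur_emu), call. = FALSE)
  steps <- seq_len(emu$n_steps)
  idx <- as.integer(round(steps * dt / ref$h)) + 1L  # into times incl. t=0
  if (any(idx > length(ref$times)))
    stop("emulator steps fall outside the reference grid", call. = FALSE)
  if (which == "v") {
    y_l <- from_levels(emu$v[steps + 1L], cfg$params$v_r, cfg$cfg$v_s)
    y_b <- ref$v_mv[idx]
  } else {
    y_l <- emu$u[steps + 1L] * cfg$params$c_m * cfg$cfg$v_s / dt
    y_b <- ref$i_pa[idx]
  }
  structure(list(y_l = y_l, y_b = y_b, n = length(y_l),
                 times = steps * dt, which = which),
            class = "paired_series")
}

#' Root-mean-square error between paired series
#'
#' `sqrt(mean((y_l - y_b)^2))`, in the units of the paired series (mV for
#' the membrane potential, pA for the current).
#'
#' @param p A `paired_series` from [align_traces()].
#' @return Non-negative scalar.
#' @export
trace_rmse <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  if (p$n < 1) stop("empty paired series", call. = FALSE)
  sqrt(mean((p$y_l - p$y_b)^2))
}

#' Pearson correlation between paired series
#'
#' The standard product-moment correlation. Affine-invariant, so the
#' result is identical whether computed on raw levels or on inverse-mapped
#' physical values.
#'
#' @param p A `paired_series` from [align_traces()].
#' @return Correlation in `[-1, 1]`.
#' @export
trace_pearson <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  if (p$n < 2) stop("need at least 2 points for a correlation", call. = FALSE)
  if (stats::sd(p$y_l) == 0 || stats::sd(p$y_b) == 0)
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  stats::cor(p$y_l, p$y_b)
}

#' Plot-ready diagnostic summaries for a paired series
#'
#' Three diagnostics for spotting discrepancies that a single averaged
#' metric can hide: (a) Gaussian-kernel density summaries of each series
#' (Silverman bandwidth), (b) value-vs-time raster arrays, and (c) the
#' scatter pairing with its least-squares trend line.
#'
#' @param p A `paired_series` from [align_traces()].
#' @return A list with `density` (per-series `x`/`y` grids), `raster`
#'   (`times`, `y_l`, `y_b`) and `scatter` (`y_b`, `y_l`, `slope`,
#'   `intercept`).
#' @export
trace_diagnostics <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  dens <- function(y) {
    if (stats::sd(y) == 0) {
      list(x = y[1], y = Inf, degenerate = TRUE)
    } else {
      d <- stats::density(y, bw = "nrd0")
      list(x = d$x, y = d$y, degenerate = FALSE)
    }
  }
  fit <- if (stats::sd(p$y_b) == 0) {
    c(intercept = NA_real_, slope = NA_real_)
  } else {
    cf <- stats::lsfit(p$y_b, p$y_l)$coefficients
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  list(density = list(emulator = dens(p$y_l), reference = dens(p$y_b)),
       raster = list(times = p$times, y_l = p$y_l, y_b = p$y_b),
       scatter = list(y_b = p$y_b, y_l = p$y_l,
                      slope = fit[["slope"]], intercept = fit[["intercept"]]))
}

#' Compare a reference and an emulator run
#'
#' Builds the full comparison report: RMSE and Pearson correlation for the
#' membrane potential and the synaptic current (each on the physical scale
#' after inverse mapping), spike counts on both backends, and the
#' diagnostic summaries.
#'
#' @inheritParams align_traces
#' @param diagnostics Include [trace_diagnostics()] output? Default `FALSE`.
#' @return An object of class `comparison_report`.
#' @export
compare_traces <- function(ref, emu, diagnostics = FALSE) {
  pv <- align_traces(ref, emu, "v")
  pu <- align_traces(ref, emu, "u")
  metr <- function(p) {
    r <- tryCatch(trace_pearson(p), error = function(e) NA_real_)
    list(rmse = trace_rmse(p), pearson_r = r, n = p$n)
  }
  structure(
    list(v = metr(pv), u = metr(pu),
         rmse = trace_rmse(pv), pearson_r = metr(pv)$pearson_r, n = pv$n,
         spike_count_ref = length(ref$spike_times),
         spike_count_emu = length(emu$spike_steps),
         diagnostics = if (diagnostics)
           list(v = trace_diagnostics(pv), u = trace_diagnostics(pu))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("cross-backend comparison report\n")
  cat(sprintf("  membrane potential: RMSE %.4g mV, r = %.6f (n = %d)\n",
              x$v$rmse, x$v$pearson_r, x$v$n))
  cat(sprintf("  synaptic current:   RMSE %.4g pA, r = %.6f\n",
              x$u$rmse, x$u$pearson_r))
  cat(sprintf("  spikes: reference %d, emulator %d\n",
              x$spike_count_ref, x$spike_count_emu))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Scalar metrics only (diagnostic arrays go to CSV via
#' [write_trace()]-style tables if needed).
#'
#' @param report A `comparison_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  out <- list(
    v = report$v, u = report$u,
    spike_count_ref = report$spike_count_ref,
    spike_count_emu = report$spike_count_emu)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path)
  structure(
    list(v = raw$v, u = raw$u,
         rmse = raw$v$rmse, pearson_r = raw$v$pearson_r, n = raw$v$n,
         spike_count_ref = raw$spike_count_ref,
         spike_count_emu = raw$spike_count_emu,
         diagnostics = NULL),
    class = "comparison_report")
}
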