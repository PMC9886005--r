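#' Read / write simulation traces as CSV
#'
#' Reference traces use columns `time_ms, v_mv, i_pa`; emulator traces use
#' `step, v_levels, u_levels`. Spike times/steps are stored in a companion
#' file by [write_spikes()]. Plain CSV dialect: header row, period decimal
#' separator.
#'
#' @param trace A `lif_trace` or `emulator_trace`.
#' @param path File path.
#' @return `read_trace()` returns a data frame with the columns above (the
#'   flavour is detectable from the header).
#' @export
write_trace <- function(trace, path) {
  df <- if (inherits(trace, "lif_trace")) {
    data.frame(time_ms = trace$times, v_mv = trace$v_mv, i_pa = trace$i_pa)
  } else if (inherits(trace, "emulator_trace")) {
    data.frame(step = trace$steps, v_levels = trace$v, u_levels = trace$u)
  } else stop("not a trace object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  ok <- all(c("time_ms", "v_mv", "i_pa") %in% names(df)) ||
    all(c("step", "v_levels", "u_levels") %in% names(df))
  if (!ok)
    stop("malformed trace file (unrecognized columns ",
         paste(names(df), collapse = ", "), "): ", path, call. = FALSE)
  df
}

#' Write spike times (or steps) as CSV
#'
#' One row per spike with SONATA-style naming: `node_id` and
#' `timestamps` (ms for reference traces, steps for emulator traces).
#'
#' @param trace A `lif_trace` or `emulator_trace`.
#' @param path File path.
#' @param node_id Id to record. Default 0.
#' @export
write_spikes <- function(trace, path, node_id = 0) {
  ts <- if (inherits(trace, "lif_trace")) trace$spike_times
  else if (inherits(trace, "emulator_trace")) trace$spike_steps
  else stop("not a trace object", call. = FALSE)
  df <- data.frame(node_id = rep(node_id, length(ts)), timestamps = ts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Recognized top-level keys: `backend` (`reference`/`emulator`/`both`),
#' `v_s`, `dt`, `duration`, `seed`, `regime`, `params` (a mapping of
#' [lif_params()] fields or a `file` path), `stimulus` (either
#' `type: bias`, `type: fixture`, `type: poisson` with its spec, or
#' `file`), and `output` paths.
#'
#' @param path YAML file path.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  out <- list(backend = "both", v_s = 1e-4, dt = 1, duration = 500,
              seed = 1, regime = "subthreshold", params = NULL,
              stimulus = list(type = "bias"), output = NULL)
  out[names(raw)] <- raw
  if (out$duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (!is.null(out$params$file) && !file.exists(out$params$file))
    stop("referenced parameter file not found: ", out$params$file,
         call. = FALSE)
  if (!is.null(out$stimulus$file) && !file.exists(out$stimulus$file))
    stop("referenced stimulus file not found: ", out$stimulus$file,
         call. = FALSE)
  out
}

# resolve the params entry of a run config into a lif_params object
resolve_params <- function(cfg) {
  p <- cfg$params
  if (is.null(p)) return(example_neuron(1))
  if (!is.null(p$file)) return(read_lif_params(p$file)[[1]])
  if (!is.null(p$example)) return(example_neuron(p$example))
  do.call(lif_params, p)
}

# resolve the stimulus entry into a spike_train_set or NULL
resolve_stimulus <- function(cfg) {
  s <- cfg$stimulus
  if (is.null(s) || identical(s$type, "bias")) return(NULL)
  if (!is.null(s$file)) return(read_spike_trains(s$file))
  if (identical(s$type, "fixture")) return(frozen_spike_fixture())
  if (identical(s$type, "poisson"))
    return(poisson_spike_trains(
      n_sources = if (is.null(s$n_sources)) 5 else s$n_sources,
      rate = if (is.null(s$rate)) 5 else s$rate,
      duration = cfg$duration, seed = cfg$seed,
      weight = if (is.null(s$weight)) NA_real_ else s$weight))
  stop("unrecognized stimulus spec", call. = FALSE)
}
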