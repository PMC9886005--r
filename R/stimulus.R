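#' A set of external spike trains
#'
#' External stimulus as per-source lists of spike times. Each source has an
#' integer id, a sorted vector of non-negative spike times (ms) and a
#' synaptic weight (pA added to the target's synaptic current per spike).
#'
#' @param times A named list of numeric vectors of spike times (ms), one
#'   per source; names are source ids (coerced to integer).
#' @param weights Per-source weights (pA); recycled to the number of
#'   sources. Default 1.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(times, weights = 1) {
  if (!is.list(times)) stop("'times' must be a list of numeric vectors",
                            call. = FALSE)
  if (is.null(names(times))) names(times) <- as.character(seq_along(times) - 1L)
  times <- lapply(times, function(tt) {
    tt <- as.numeric(tt)
    if (any(!is.finite(tt)) || any(tt < 0))
      stop("spike times must be finite and non-negative", call. = FALSE)
    sort(tt)
  })
  weights <- rep_len(as.numeric(weights), length(times))
  structure(list(times = times, weights = weights), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("spike train set: %d sources, %d events\n",
              length(x$times), sum(lengths(x$times))))
  for (i in seq_along(x$times))
    cat(sprintf("  source %s (w = %g pA): %s\n", names(x$times)[i],
                x$weights[i], paste(x$times[[i]], collapse = ", ")))
  invisible(x)
}

#' Total event count of a spike train set
#' @param x A [spike_train_set()].
#' @return Integer number of spikes across all sources.
#' @export
n_spikes <- function(x) sum(lengths(x$times))

#' The frozen five-source spike fixture
#'
#' The fixed external stimulus used by the worked single-neuron examples:
#' five sources, eleven spike times in 500 ms, originally drawn from a
#' 5 Hz Poisson generator and then frozen so every run sees the same input.
#'
#' @param weight Per-source synaptic weight (pA). The default `NA` marks
#'   the weights as "use the target neuron's `w_syn`": [run_single_neuron()]
#'   and the other experiment drivers substitute the neuron's documented
#'   ~1 mV-peak default. Pass a number to fix the weight explicitly.
#' @return A [spike_train_set()] with sources 0..4.
#' @export
frozen_spike_fixture <- function(weight = NA_real_) {
  s <- spike_train_set(list(
    "0" = 446,
    "1" = 355,
    "2" = c(53, 258, 300, 424, 457),
    "3" = c(88, 466),
    "4" = c(100, 212)))
  s$weights[] <- weight
  s
}

#' Seeded homogeneous Poisson spike trains
#'
#' Independent homogeneous Poisson processes, one per source, at a common
#' rate. The generator is seeded and restores the caller's RNG state, so a
#' given spec always produces the same ("frozen") trains.
#'
#' @param n_sources Number of sources (>= 1).
#' @param rate Firing rate (Hz, >= 0).
#' @param duration Window length (ms).
#' @param seed Integer seed.
#' @param weight Per-source weight (pA). Default 1.
#' @return A [spike_train_set()].
#' @export
poisson_spike_trains <- function(n_sources = 5, rate = 5, duration = 500,
                                 seed = 1, weight = 1) {
  stopifnot(n_sources >= 1, rate >= 0, duration > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rate_ms <- rate / 1000  # events per ms
  times <- lapply(seq_len(n_sources), function(i) {
    if (rate_ms == 0) return(numeric(0))
    # oversample exponential gaps past the window
    n_guess <- max(10, ceiling(rate_ms * duration * 3))
    tt <- cumsum(stats::rexp(n_guess, rate_ms))
    while (length(tt) && tt[length(tt)] < duration)
      tt <- c(tt, tt[length(tt)] + cumsum(stats::rexp(n_guess, rate_ms)))
    tt[tt < duration]
  })
  names(times) <- as.character(seq_len(n_sources) - 1L)
  spike_train_set(times, weights = weight)
}

#' Read / write spike trains as two-column CSV
#'
#' Columns `source_id` and `time_ms`, one row per spike (SONATA-style
#' node-id/timestamp naming). Weights are stored in an optional third
#' column `weight_pa`.
#'
#' @param spikes A [spike_train_set()].
#' @param path File path.
#' @return `read_spike_trains()` returns a [spike_train_set()].
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  ids <- names(spikes$times)
  df <- do.call(rbind, lapply(seq_along(ids), function(i) {
    tt <- spikes$times[[i]]
    if (!length(tt)) return(NULL)
    data.frame(source_id = ids[i], time_ms = tt,
               weight_pa = spikes$weights[i])
  }))
  if (is.null(df))
    df <- data.frame(source_id = character(0), time_ms = numeric(0),
                     weight_pa = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(source_id = "character"))
  if (!all(c("source_id", "time_ms") %in% names(df)))
    stop("malformed spike file (need columns source_id, time_ms): ", path,
         call. = FALSE)
  ids <- unique(df$source_id)
  times <- lapply(ids, function(id) df$time_ms[df$source_id == id])
  names(times) <- ids
  w <- if ("weight_pa" %in% names(df))
    vapply(ids, function(id) df$weight_pa[df$source_id == id][1], 0) else 1
  spike_train_set(times, weights = w)
}
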