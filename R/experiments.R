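#' Single-neuron cross-backend validation
#'
#' Runs the same neuron on both backends — exact integration in physical
#' units and the fixed-point emulator — under the same stimulus, and
#' reports agreement after inverse mapping. The default setup mirrors the
#' worked examples: 500 ms, `dt = 1` ms/step, `v_s = 1e-4` mV/level.
#'
#' The `regime` argument selects whether threshold/reset is applied.
#' `"subthreshold"` (default) records the free membrane trajectory, the
#' regime under which the worked single-neuron comparisons are defined;
#' `"spiking"` applies the strict threshold and reset on both backends.
#'
#' @param params A [lif_params()] object.
#' @param stimulus A [spike_train_set()] or `NULL` (bias-only).
#' @param cfg A [mapping_config()].
#' @param duration Simulated time (ms). Default 500.
#' @param h Reference grid step (ms). Default `min(1, cfg$dt)`.
#' @param regime `"subthreshold"` or `"spiking"`.
#' @param diagnostics Include diagnostic summaries in the report.
#' @param clamp_decay Passed to [map_neuron()].
#' @return A `comparison_report` (see [compare_traces()]).
#' @export
#' @examples
#' rep <- run_single_neuron(example_neuron(1), NULL, mapping_config(),
#'                          duration = 200)
#' rep$v$pearson_r
run_single_neuron <- function(params, stimulus = NULL,
                              cfg = mapping_config(), duration = 500,
                              h = min(1, cfg$dt),
                              regime = c("subthreshold", "spiking"),
                              diagnostics = FALSE, clamp_decay = FALSE) {
  regime <- match.arg(regime)
  thr <- regime == "spiking"
  if (!is.null(stimulus) && is.na(params$w_syn))
    stop("neuron has no synaptic weight for spike stimulus", call. = FALSE)
  stim <- stimulus
  if (!is.null(stim)) stim$weights[] <- ifelse(is.finite(stim$weights),
                                               stim$weights, params$w_syn)
  hw <- map_neuron(params, cfg, clamp_decay = clamp_decay)
  ref <- run_reference(params, stim, duration = duration, h = h,
                       apply_threshold = thr)
  emu <- run_emulator(hw, stim, n_steps = as.integer(round(duration / cfg$dt)),
                      apply_threshold = thr)
  compare_traces(ref, emu, diagnostics = diagnostics)
}

#' Temporal-precision sweep
#'
#' Re-maps and re-runs the same neuron and stimulus at several temporal
#' scales `dt` (ms per hardware step) and tabulates RMSE and correlation
#' for both state variables. The reference grid is `min(1, dt)` and the
#' comparison happens on the emulator grid. Rows whose time constants are
#' not representable at a given `dt` are run with the decay clamped at
#' 4096 (complete decay per step) and flagged in the `clamped` column;
#' rows that fail to map entirely are flagged in `error`.
#'
#' @inheritParams run_single_neuron
#' @param dts Temporal scales to try (ms/step). Default `c(0.1, 1, 10)`.
#' @param v_s Voltage scale held fixed across the sweep. Default `1e-4`.
#' @return A data frame of class `sweep_result` with one row per `dt`:
#'   `dt, n_steps, v_rmse, v_r, u_rmse, u_r, clamped, error`.
#' @export
sweep_dt <- function(params, stimulus = NULL, dts = c(0.1, 1, 10),
                     v_s = 1e-4, duration = 500,
                     regime = c("subthreshold", "spiking")) {
  regime <- match.arg(regime)
  rows <- lapply(dts, function(dt) {
    cfg <- mapping_config(v_s = v_s, dt = dt)
    res <- tryCatch({
      hw <- map_neuron(params, cfg, clamp_decay = TRUE)
      rep <- run_single_neuron(params, stimulus, cfg, duration = duration,
                               regime = regime, clamp_decay = TRUE)
      data.frame(dt = dt, n_steps = as.integer(round(duration / dt)),
                 v_rmse = rep$v$rmse, v_r = rep$v$pearson_r,
                 u_rmse = rep$u$rmse, u_r = rep$u$pearson_r,
                 clamped = hw$decay_clamped, error = NA_character_)
    }, error = function(e)
      data.frame(dt = dt, n_steps = as.integer(round(duration / dt)),
                 v_rmse = NA_real_, v_r = NA_real_, u_rmse = NA_real_,
                 u_r = NA_real_, clamped = NA,
                 error = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "axis") <- "dt"
  out
}

#' Voltage-precision sweep
#'
#' Re-maps and re-runs the same neuron and stimulus at several voltage
#' scales `v_s` (mV per level) with `dt` held fixed. Rows whose threshold
#' or bias overflow at a fine `v_s` are flagged, not fatal.
#'
#' @inheritParams sweep_dt
#' @param vs Voltage scales to try (mV/level).
#'   Default `c(1e-3, 1e-4, 1e-5)`.
#' @param dt Temporal scale held fixed. Default 1.
#' @return A data frame of class `sweep_result`, one row per `v_s`.
#' @export
sweep_vs <- function(params, stimulus = NULL, vs = c(1e-3, 1e-4, 1e-5),
                     dt = 1, duration = 500,
                     regime = c("subthreshold", "spiking")) {
  regime <- match.arg(regime)
  rows <- lapply(vs, function(v_s) {
    cfg <- mapping_config(v_s = v_s, dt = dt)
    tryCatch({
      rep <- run_single_neuron(params, stimulus, cfg, duration = duration,
                               regime = regime)
      data.frame(v_s = v_s, v_rmse = rep$v$rmse, v_r = rep$v$pearson_r,
                 u_rmse = rep$u$rmse, u_r = rep$u$pearson_r,
                 error = NA_character_)
    }, error = function(e)
      data.frame(v_s = v_s, v_rmse = NA_real_, v_r = NA_real_,
                 u_rmse = NA_real_, u_r = NA_real_,
                 error = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "axis") <- "v_s"
  out
}

#' Synthetic multi-class neuron parameter table
#'
#' A seeded stand-in for a catalogue of cortical neuron classes: half
#' excitatory, half inhibitory, with membrane time constants in
#' `[10, 50]` ms, capacitances in `[80, 300]` pF and bias currents in
#' `[50, 250]` pA (all uniform). Excitatory and inhibitory classes share
#' the parameter ranges; the label drives the sign of the network weight
#' when the table seeds a network. This is synthetic data — it emulates
#' the spread of catalogued parameters, not any measured cell.
#'
#' @param n Number of classes (even). Default 20.
#' @param seed Integer seed.
#' @return A data frame with columns `class` (`"excitatory"` /
#'   `"inhibitory"`), `c_m`, `tau_v`, `e_l`, `v_r`, `theta`, `i_bias`,
#'   `tau_syn`.
#' @export
synthetic_neuron_classes <- function(n = 20, seed = 1) {
  stopifnot(n >= 2, n %% 2 == 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(
    class = rep(c("excitatory", "inhibitory"), each = n / 2),
    c_m = stats::runif(n, 80, 300),
    tau_v = stats::runif(n, 10, 50),
    e_l = -70, v_r = -70, theta = -43,
    i_bias = stats::runif(n, 50, 250),
    tau_syn = 5)
}

#' Ensemble validation over a table of neuron classes
#'
#' Maps and simulates every row of a parameter table as an independent
#' (unconnected) compartment on both backends and reports per-class and
#' aggregate agreement, plus the parameter scatter data (`c_m` vs `tau_v`
#' and `i_bias` vs `tau_v`, sized by RMSE).
#'
#' @param param_table Data frame as from [synthetic_neuron_classes()], or
#'   a list of [lif_params()] (then `class` defaults to `"excitatory"`).
#' @param stimulus Shared [spike_train_set()] or `NULL` (bias-only).
#' @param cfg A [mapping_config()].
#' @param duration Simulated time (ms). Default 500.
#' @param regime Passed to [run_single_neuron()].
#' @return An object of class `ensemble_result`: list with `reports`
#'   (per-class `comparison_report`), `classes`, `failed` (row ids whose
#'   mapping failed, with messages), `summary` (per-class-label mean r and
#'   RMSE), `mean_r`, `mean_rmse`, and `scatter` (per-row parameters and
#'   RMSE).
#' @export
run_ensemble <- function(param_table, stimulus = NULL,
                         cfg = mapping_config(), duration = 500,
                         regime = c("subthreshold", "spiking")) {
  regime <- match.arg(regime)
  if (is.data.frame(param_table)) {
    classes <- if ("class" %in% names(param_table))
      as.character(param_table$class) else rep("excitatory", nrow(param_table))
    plist <- lapply(seq_len(nrow(param_table)), function(i) {
      row <- param_table[i, ]
      lif_params(c_m = row$c_m, tau_v = row$tau_v, e_l = row$e_l,
                 v_r = row$v_r, theta = row$theta, i_bias = row$i_bias,
                 tau_syn = if ("tau_syn" %in% names(row)) row$tau_syn else 5)
    })
  } else {
    plist <- param_table
    classes <- rep("excitatory", length(plist))
  }
  n <- length(plist)
  reports <- vector("list", n)
  failed <- list()
  for (i in seq_len(n)) {
    reports[[i]] <- tryCatch(
      run_single_neuron(plist[[i]], stimulus, cfg, duration = duration,
                        regime = regime),
      error = function(e) {
        failed[[length(failed) + 1L]] <<- list(row = i,
                                               message = conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(reports, is.null, TRUE)
  r_all <- vapply(reports[ok], function(x) x$v$pearson_r, 0)
  rmse_all <- vapply(reports[ok], function(x) x$v$rmse, 0)
  summ <- do.call(rbind, lapply(unique(classes[ok]), function(cl) {
    sel <- classes[ok] == cl
    data.frame(class = cl, n = sum(sel), mean_r = mean(r_all[sel]),
               mean_rmse = mean(rmse_all[sel]))
  }))
  scatter <- data.frame(
    row = which(ok), class = classes[ok],
    c_m = vapply(plist[ok], `[[`, 0, "c_m"),
    tau_v = vapply(plist[ok], `[[`, 0, "tau_v"),
    i_bias = vapply(plist[ok], `[[`, 0, "i_bias"),
    rmse = rmse_all)
  structure(list(reports = reports, classes = classes, failed = failed,
                 summary = summ, mean_r = mean(r_all),
                 mean_rmse = mean(rmse_all), scatter = scatter),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble result: %d classes (%d failed to map)\n",
              length(x$reports), length(x$failed)))
  print(x$summary, row.names = FALSE)
  cat(sprintf("  aggregate: mean r = %.6f, mean RMSE = %.4g mV\n",
              x$mean_r, x$mean_rmse))
  invisible(x)
}

#' Random excitatory/inhibitory network
#'
#' Erdős–Rényi directed connectivity: every ordered pair (no
#' self-connections) is connected independently with probability `p`.
#' Half the compartments are excitatory (positive synaptic weight), half
#' inhibitory (negative), and all are driven by their bias current.
#' Seeded and reproducible.
#'
#' @param n Number of compartments.
#' @param p Connection probability in `[0, 1]`. Default 0.1.
#' @param params A [lif_params()] shared by all compartments; default the
#'   bias-driven worked example set.
#' @param cfg A [mapping_config()].
#' @param weight Synapse magnitude in levels; excitatory edges get `+`,
#'   inhibitory `-`. Default 50 (small enough to avoid register overflow
#'   in large nets).
#' @param seed Integer seed.
#' @return A [network_spec()] with an `ei` attribute labelling
#'   compartments.
#' @export
build_random_network <- function(n, p = 0.1, params = example_neuron(1),
                                 cfg = mapping_config(), weight = 50,
                                 seed = 1) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hw <- map_neuron(params, cfg)
  configs <- rep(list(hw), n)
  ei <- rep(c("excitatory", "inhibitory"), length.out = n)
  pre <- integer(0); post <- integer(0)
  if (p > 0) {
    pairs <- which(matrix(stats::runif(n * n), n, n) < p, arr.ind = TRUE)
    keep <- pairs[, 1] != pairs[, 2]
    pre <- pairs[keep, 1]; post <- pairs[keep, 2]
  }
  w <- ifelse(ei[pre] == "excitatory", weight, -weight)
  spec <- network_spec(configs,
                       edges = data.frame(pre = pre, post = post,
                                          weight = as.numeric(w)))
  attr(spec, "ei") <- ei
  spec
}

#' Runtime scaling study
#'
#' Wall-clock runtime of the emulator for connected and unconnected
#' networks of increasing size. Informational only: runtimes depend on the
#' host and are never part of any validation surface.
#'
#' @param sizes Ascending network sizes.
#' @param p Connection probability for the connected variant. Default 0.1.
#' @param duration Simulated time (ms). Default 500.
#' @param cfg A [mapping_config()].
#' @param params Shared neuron parameters.
#' @param seed Integer seed.
#' @return A data frame: `n`, `connected_s`, `unconnected_s`, `error`.
#' @export
scaling_study <- function(sizes, p = 0.1, duration = 500,
                          cfg = mapping_config(),
                          params = example_neuron(1), seed = 1) {
  stopifnot(all(diff(sizes) > 0) || length(sizes) == 1)
  n_steps <- as.integer(round(duration / cfg$dt))
  rows <- lapply(sizes, function(n) {
    res <- tryCatch({
      con <- build_random_network(n, p = p, params = params, cfg = cfg,
                                  seed = seed)
      unc <- build_random_network(n, p = 0, params = params, cfg = cfg,
                                  seed = seed)
      t_con <- system.time(run_network(con, n_steps, record = FALSE,
                                       saturate = TRUE))[["elapsed"]]
      t_unc <- system.time(run_network(unc, n_steps, record = FALSE,
                                       saturate = TRUE))[["elapsed"]]
      data.frame(n = n, connected_s = t_con, unconnected_s = t_unc,
                 error = NA_character_)
    }, error = function(e)
      data.frame(n = n, connected_s = NA_real_, unconnected_s = NA_real_,
                 error = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}
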