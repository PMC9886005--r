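#' Fixed-point decay multiply
#'
#' The hardware decays a 23-bit state by multiplying with
#' `(4096 - delta)` and arithmetically shifting right by 12 bits, i.e.
#' floor division by 4096 (floors toward negative infinity for negative
#' states). The intermediate product fits in 35 bits, which doubles
#' represent exactly.
#'
#' @param x Integer state value(s), `|x| < 2^23`.
#' @param delta Decay constant in `[1, 4096]`.
#' @return Decayed integer value(s).
#' @export
#' @examples
#' decay_multiply(4096, 164)  # 3932
#' decay_multiply(-1, 164)    # -1 (floor semantics)
decay_multiply <- function(x, delta) {
  stopifnot(all(delta >= 1), all(delta <= .DECAY_MAX))
  floor(x * (.DECAY_MAX - delta) / .DECAY_MAX)
}

#' One hardware compartment update
#'
#' The per-step update rule of the fixed-point compartment: the current
#' state decays and receives afferent spike increments, then the voltage
#' decays and receives the bias plus the updated current,
#' `v(t+1) = v(t)*(1 - delta_v/4096) + b + u(t+1)`; finally the threshold
#' is tested strictly (`v > theta_hw`) and `v` resets to 0 on a spike.
#' State magnitudes are checked against the 23-bit registers after each
#' update.
#'
#' @param state A list with integer `v`, `u` and step counter `t`.
#' @param cfg A `loihi_config` from [map_neuron()].
#' @param spike_increment Summed afferent weight arriving this step
#'   (levels).
#' @param apply_threshold Test and reset the threshold? Default `TRUE`.
#' @param saturate On register overflow, clip to `+/-(2^23 - 1)` instead of
#'   erroring. Default `FALSE` (fail loudly).
#' @return A list with the new `state` and logical `spiked`.
#' @export
emulator_step <- function(state, cfg, spike_increment = 0,
                          apply_threshold = TRUE, saturate = FALSE) {
  chk <- function(x, nm, t) {
    if (abs(x) >= .STATE_MAX) {
      if (saturate) return(sign(x) * (.STATE_MAX - 1))
      stop(sprintf("state overflow: |%s| = %.0f >= 2^23 at step %d", nm,
                   abs(x), t), call. = FALSE)
    }
    x
  }
  t1 <- state$t + 1L
  u <- chk(decay_multiply(state$u, cfg$delta_u) + spike_increment, "u", t1)
  v <- chk(decay_multiply(state$v, cfg$delta_v) + cfg$bias + u, "v", t1)
  spiked <- FALSE
  if (apply_threshold && v > cfg$theta_hw) {
    spiked <- TRUE
    v <- 0
  }
  list(state = list(v = v, u = u, t = t1), spiked = spiked)
}

#' Schedule spike times onto hardware steps
#'
#' Maps each physical spike time (ms) to hardware step `round(t/dt)`
#' (times earlier than half a step are delivered at step 1); multiple
#' arrivals at one step sum their increments.
#'
#' @param times Spike times (ms), non-negative.
#' @param dt Temporal scale (ms per step).
#' @param n_steps Simulation horizon in steps.
#' @param increments Per-spike increment (levels); recycled. Default 1.
#' @return Numeric vector of length `n_steps`: summed increment per step.
#' @export
#' @examples
#' schedule_spikes(c(53, 258, 300, 424, 457), dt = 1, n_steps = 500)[53]
schedule_spikes <- function(times, dt, n_steps, increments = 1) {
  if (any(times < 0)) stop("spike times must be non-negative", call. = FALSE)
  increments <- rep_len(increments, length(times))
  out <- numeric(n_steps)
  for (i in seq_along(times)) {
    s <- max(1L, as.integer(floor(times[i] / dt + 0.5)))
    if (s > n_steps)
      stop(sprintf("spike at %g ms maps to step %d beyond the %d-step horizon",
                   times[i], s, n_steps), call. = FALSE)
    out[s] <- out[s] + increments[i]
  }
  out
}

#' Run the fixed-point compartment emulator
#'
#' Bit-faithful software execution of a single hardware compartment for
#' `n_steps` steps. States are integers in 23-bit registers; the update
#' rule and rounding follow [emulator_step()]. Deterministic: identical
#' config and stimulus give bit-identical traces.
#'
#' With `quantize = FALSE` the emulator runs the same recursion with
#' real-valued states and the exact (unrounded) decay factors
#' `1 - dt/tau`, which is precisely forward-Euler integration of the
#' continuous model in level units — useful for separating quantization
#' error from time-discretization error.
#'
#' @param cfg A `loihi_config` from [map_neuron()].
#' @param stimulus A [spike_train_set()] (weights in pA are mapped to level
#'   increments via [map_weight()]), a numeric vector of per-step level
#'   increments of length `n_steps`, or `NULL`.
#' @param n_steps Number of steps; default `round(500 / dt)`.
#' @param v0 Initial voltage state (levels); default `cfg$v0`.
#' @param apply_threshold,saturate Passed to [emulator_step()].
#' @param quantize Use integer states and quantized decays (`TRUE`,
#'   default) or the real-valued Euler variant (`FALSE`).
#' @return An object of class `emulator_trace`: list with `steps`
#'   (0..n_steps), `v` and `u` (levels, length `n_steps + 1`),
#'   `spike_steps`, and the config used.
#' @export
#' @examples
#' cfg <- map_neuron(example_neuron(1), mapping_config())
#' tr <- run_emulator(cfg, n_steps = 100, apply_threshold = FALSE)
#' tail(tr$v, 1)
run_emulator <- function(cfg, stimulus = NULL, n_steps = NULL, v0 = cfg$v0,
                         apply_threshold = TRUE, saturate = FALSE,
                         quantize = TRUE) {
  stopifnot(inherits(cfg, "loihi_config"))
  dt <- cfg$cfg$dt
  if (is.null(n_steps)) n_steps <- as.integer(round(500 / dt))
  inc <- if (is.null(stimulus)) {
    numeric(n_steps)
  } else if (inherits(stimulus, "spike_train_set")) {
    Reduce(`+`, lapply(seq_along(stimulus$times), function(i) {
      w_hw <- map_weight(stimulus$weights[i], cfg$params, cfg$cfg)
      schedule_spikes(stimulus$times[[i]], dt, n_steps, increments = w_hw)
    }), numeric(n_steps))
  } else {
    stopifnot(is.numeric(stimulus), length(stimulus) == n_steps)
    stimulus
  }

  if (quantize) {
    dec_v <- function(x) decay_multiply(x, cfg$delta_v)
    dec_u <- function(x) decay_multiply(x, cfg$delta_u)
    bias <- cfg$bias
  } else {
    raw_v <- compute_decay(cfg$params$tau_v, dt, clamp = TRUE)$raw
    raw_u <- compute_decay(cfg$params$tau_syn, dt, clamp = TRUE)$raw
    dec_v <- function(x) x * (1 - min(raw_v, .DECAY_MAX) / .DECAY_MAX)
    dec_u <- function(x) x * (1 - min(raw_u, .DECAY_MAX) / .DECAY_MAX)
    bias <- compute_bias(cfg$params, cfg$cfg)
  }

  v <- numeric(n_steps + 1L); u <- numeric(n_steps + 1L)
  v[1] <- v0; u[1] <- 0
  spikes <- integer(0)
  vv <- v0; uu <- 0
  chk <- function(x, nm, t) {
    if (abs(x) >= .STATE_MAX) {
      if (saturate) return(sign(x) * (.STATE_MAX - 1))
      stop(sprintf("state overflow: |%s| = %.0f >= 2^23 at step %d",
                   nm, abs(x), t), call. = FALSE)
    }
    x
  }
  for (k in seq_len(n_steps)) {
    uu <- chk(dec_u(uu) + inc[k], "u", k)
    vv <- chk(dec_v(vv) + bias + uu, "v", k)
    if (apply_threshold && vv > cfg$theta_hw) {
      spikes <- c(spikes, k)
      vv <- 0
    }
    v[k + 1L] <- vv; u[k + 1L] <- uu
  }
  structure(list(steps = 0:n_steps, v = v, u = u, spike_steps = spikes,
                 n_steps = n_steps, config = cfg, quantized = quantize),
            class = "emulator_trace")
}

#' @export
print.emulator_trace <- function(x, ...) {
  cat(sprintf("emulator trace: %d steps (dt = %g ms/step), %d spikes%s\n",
              x$n_steps, x$config$cfg$dt, length(x$spike_steps),
              if (x$quantized) "" else " [unquantized]"))
  cat(sprintf("  v in [%.0f, %.0f] levels, u in [%.0f, %.0f] levels\n",
              min(x$v), max(x$v), min(x$u), max(x$u)))
  invisible(x)
}

#' A multi-compartment network specification
#'
#' Directed weighted network of hardware compartments with per-compartment
#' external stimulus. A spike emitted by compartment `pre` at step `t` is
#' delivered to the current state of `post` at step `t + 1` (synchronous
#' two-phase update, one-step latency).
#'
#' @param configs List of `loihi_config`, one per compartment. All must
#'   share the same mapping config.
#' @param edges Data frame with columns `pre`, `post` (1-based compartment
#'   indices) and `weight` (levels per spike, integer); may have zero rows.
#' @param stimuli Optional list (length = compartments) of per-compartment
#'   stimuli as accepted by [run_emulator()].
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(configs, edges = NULL, stimuli = NULL) {
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, TRUE, "loihi_config")))
  n <- length(configs)
  if (is.null(edges))
    edges <- data.frame(pre = integer(0), post = integer(0),
                        weight = numeric(0))
  stopifnot(all(c("pre", "post", "weight") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$pre >= 1), all(edges$pre <= n),
              all(edges$post >= 1), all(edges$post <= n))
    if (any(abs(edges$weight) >= .STATE_MAX))
      stop("edge weight out of 23-bit range", call. = FALSE)
    if (any(edges$pre == edges$post))
      warning("network contains self-connections", call. = FALSE)
  }
  if (!is.null(stimuli)) stopifnot(length(stimuli) == n)
  structure(list(configs = configs, edges = edges, stimuli = stimuli,
                 n = n), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network spec: %d compartments, %d synapses\n", x$n,
              nrow(x$edges)))
  invisible(x)
}

#' Run a network of hardware compartments
#'
#' All compartments advance synchronously; spikes emitted at step `t` are
#' added to their targets' current states at step `t + 1`.
#'
#' @param spec A [network_spec()].
#' @param n_steps Number of steps.
#' @param record Record full state traces (`TRUE`, default) or only spike
#'   steps (`FALSE`, cheaper for scaling runs).
#' @param saturate Clip on register overflow instead of erroring.
#' @return A list with `v`, `u` (matrices `n_steps + 1` x n, when
#'   `record`), `spike_steps` (list per compartment) and `n_steps`.
#' @export
run_network <- function(spec, n_steps, record = TRUE, saturate = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n
  dt <- spec$configs[[1]]$cfg$dt
  delta_v <- vapply(spec$configs, `[[`, 0L, "delta_v")
  delta_u <- vapply(spec$configs, `[[`, 0L, "delta_u")
  bias <- vapply(spec$configs, `[[`, 0, "bias")
  theta <- vapply(spec$configs, `[[`, 0L, "theta_hw")
  v0 <- vapply(spec$configs, `[[`, 0L, "v0")

  ext <- matrix(0, n_steps, n)
  if (!is.null(spec$stimuli)) {
    for (j in seq_len(n)) {
      s <- spec$stimuli[[j]]
      if (is.null(s)) next
      if (inherits(s, "spike_train_set")) {
        for (i in seq_along(s$times)) {
          w_hw <- map_weight(s$weights[i], spec$configs[[j]]$params,
                             spec$configs[[j]]$cfg)
          ext[, j] <- ext[, j] +
            schedule_spikes(s$times[[i]], dt, n_steps, increments = w_hw)
        }
      } else {
        ext[, j] <- rep_len(s, n_steps)
      }
    }
  }

  # adjacency: delivered[post] = sum of weights from pre that spiked
  W <- NULL
  if (nrow(spec$edges))
    W <- Matrix_free_adjacency(spec$edges, n)

  vv <- as.numeric(v0); uu <- numeric(n)
  vrec <- if (record) matrix(0, n_steps + 1L, n) else NULL
  urec <- if (record) matrix(0, n_steps + 1L, n) else NULL
  if (record) { vrec[1, ] <- vv; urec[1, ] <- uu }
  spikes <- rep(list(integer(0)), n)
  pending <- numeric(n)  # synaptic input scheduled for this step
  cap <- .STATE_MAX - 1
  for (k in seq_len(n_steps)) {
    uu <- floor(uu * (.DECAY_MAX - delta_u) / .DECAY_MAX) + ext[k, ] + pending
    vv <- floor(vv * (.DECAY_MAX - delta_v) / .DECAY_MAX) + bias + uu
    bad <- abs(uu) >= .STATE_MAX | abs(vv) >= .STATE_MAX
    if (any(bad)) {
      if (!saturate)
        stop(sprintf("state overflow in compartment %d at step %d",
                     which(bad)[1], k), call. = FALSE)
      uu <- pmin(pmax(uu, -cap), cap)
      vv <- pmin(pmax(vv, -cap), cap)
    }
    fired <- vv > theta
    if (any(fired)) {
      for (j in which(fired)) spikes[[j]] <- c(spikes[[j]], k)
      vv[fired] <- 0
    }
    pending <- if (is.null(W)) numeric(n) else as.numeric(fired %*% W)
    if (record) { vrec[k + 1L, ] <- vv; urec[k + 1L, ] <- uu }
  }
  list(v = vrec, u = urec, spike_steps = spikes, n_steps = n_steps,
       spec = spec)
}

# dense adjacency matrix (pre x post); networks here are small enough
Matrix_free_adjacency <- function(edges, n) {
  W <- matrix(0, n, n)
  for (i in seq_len(nrow(edges)))
    W[edges$pre[i], edges$post[i]] <- W[edges$pre[i], edges$post[i]] +
      edges$weight[i]
  W
}

#' Extract one compartment of a network run as an `emulator_trace`
#'
#' @param run Result of [run_network()] with `record = TRUE`.
#' @param j Compartment index.
#' @return An `emulator_trace`.
#' @export
network_trace <- function(run, j) {
  stopifnot(!is.null(run$v))
  structure(list(steps = 0:run$n_steps, v = run$v[, j], u = run$u[, j],
                 spike_steps = run$spike_steps[[j]], n_steps = run$n_steps,
                 config = run$spec$configs[[j]], quantized = TRUE),
            class = "emulator_trace")
}
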