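# Bit-layout constants of the hardware compartment
.STATE_BITS <- 23L          # membrane potential and current: +/- 2^23 levels
.DECAY_BITS <- 12L          # decay constants: 12-bit, 0 encodes 4096
.THETA_LOW_BITS <- 6L       # threshold is the 17 high bits of a 23-bit word
.STATE_MAX <- 2^23
.DECAY_MAX <- 2^12
.BIAS_MANT_MAX <- 2^12
.BIAS_EXP_MAX <- 7L

#' Forward voltage transform: physical mV to hardware levels
#'
#' The hardware state is a dimensionless integer; physical membrane
#' potentials are shifted so that the reset maps to zero (the hardware
#' reset value) and re-scaled by the voltage scale `v_s`:
#' `v = (V - v_r) / v_s`. No rounding is applied here.
#'
#' @param v_mv Membrane potential(s), mV.
#' @param v_r Reset potential, mV.
#' @param v_s Voltage scale, mV per level (> 0).
#' @return Level value(s), real (not yet quantized).
#' @seealso [from_levels()] for the inverse.
#' @export
to_levels <- function(v_mv, v_r, v_s) {
  if (!all(is.finite(v_mv)) || !is.finite(v_r) || !is.finite(v_s))
    stop("non-finite input to 'to_levels'", call. = FALSE)
  if (v_s <= 0) stop("'v_s' must be positive", call. = FALSE)
  (v_mv - v_r) / v_s
}

#' Inverse voltage transform: hardware levels to physical mV
#'
#' `V = v * v_s + v_r`; exact inverse of [to_levels()].
#'
#' @param v Level value(s).
#' @inheritParams to_levels
#' @return Membrane potential(s), mV.
#' @export
from_levels <- function(v, v_r, v_s) {
  if (!all(is.finite(v)) || !is.finite(v_r) || !is.finite(v_s))
    stop("non-finite input to 'from_levels'", call. = FALSE)
  if (v_s <= 0) stop("'v_s' must be positive", call. = FALSE)
  v * v_s + v_r
}

#' Quantize a time constant into a 12-bit decay
#'
#' The hardware decays a state per step by multiplying with
#' `(4096 - delta)/4096`; equating this with the Euler factor
#' `1 - dt/tau` gives `delta = (dt/tau) * 2^12`. The 12-bit register
#' restricts `delta` to `[1, 4096]`, i.e. `dt <= tau <= 4096*dt`.
#'
#' @param tau Time constant (ms), positive.
#' @param dt Temporal scale (ms per step), positive.
#' @param clamp If `TRUE`, a raw decay above 4096 (i.e. `tau < dt`) is
#'   saturated to 4096 — complete decay within one step, the closest value
#'   the register can hold — instead of raising an error. Used by the
#'   temporal-precision sweep where `dt` deliberately exceeds `tau_syn`.
#' @return A list with `raw` (the real-valued decay `(dt/tau)*4096`) and
#'   `delta` (nearest integer in `[1, 4096]`).
#' @export
#' @examples
#' compute_decay(25, 1)   # raw 163.84, delta 164
compute_decay <- function(tau, dt, clamp = FALSE) {
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  raw <- (dt / tau) * .DECAY_MAX
  if (raw > .DECAY_MAX) {
    if (!clamp)
      stop(sprintf("decay overflow: tau = %g ms < dt = %g ms/step (raw decay %.4g > 4096)",
                   tau, dt, raw), call. = FALSE)
    return(list(raw = raw, delta = as.integer(.DECAY_MAX), clamped = TRUE))
  }
  if (raw < 0.5)  # would round to 0, i.e. tau > 2*4096*dt
    stop(sprintf("time constant unrepresentable: tau = %g ms > 4096 * dt = %g ms",
                 tau, max_representable_tau(dt)), call. = FALSE)
  delta <- floor(raw + 0.5)  # nearest, half away from zero
  if (delta < 1) delta <- 1
  if (tau > max_representable_tau(dt))
    stop(sprintf("time constant unrepresentable: tau = %g ms > 4096 * dt = %g ms",
                 tau, max_representable_tau(dt)), call. = FALSE)
  list(raw = raw, delta = as.integer(delta), clamped = FALSE)
}

#' Largest time constant representable at a given temporal scale
#'
#' The 12-bit decay forces `delta >= 1`, i.e. `tau <= 4096 * dt`. At
#' `dt = 0.01` ms/step this caps representable membrane time constants at
#' 40.96 ms, which already excludes some catalogued neuron models.
#'
#' @inheritParams compute_decay
#' @return Maximum representable `tau` (ms).
#' @export
max_representable_tau <- function(dt) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  .DECAY_MAX * dt
}

#' Effective per-step input drive (bias) in hardware units
#'
#' The constant part of the hardware current state per step:
#' `b = [i_bias/(c_m * v_s) + (e_l - v_r)/(tau_v * v_s)] * dt` (levels per
#' step). The second term is the reference drive left over when the resting
#' potential differs from the reset; it vanishes when `e_l == v_r`.
#'
#' @param params A [lif_params()] object.
#' @param cfg A [mapping_config()] object.
#' @return Bias `b` (levels per step, real).
#' @export
compute_bias <- function(params, cfg) {
  b <- (params$i_bias / (params$c_m * cfg$v_s) +
          (params$e_l - params$v_r) / (params$tau_v * cfg$v_s)) * cfg$dt
  if (abs(b) >= .STATE_MAX)
    stop(sprintf("bias overflow: |b| = %.4g >= 2^23 levels/step", abs(b)),
         call. = FALSE)
  b
}

#' Encode a bias as mantissa and exponent
#'
#' The hardware stores the constant input as `m * 2^e` with
#' `m` in `[-4096, 4096]` and `e` in `[0, 7]`. The encoding minimizes the
#' absolute encoding error over the full (m, e) grid; ties are broken
#' toward the smallest exponent (finest granularity).
#'
#' @param b Target bias (levels per step).
#' @return A list with `mantissa`, `exponent` and `value = mantissa * 2^exponent`.
#' @export
quantize_bias <- function(b) {
  if (!is.finite(b)) stop("non-finite bias", call. = FALSE)
  if (abs(b) > .BIAS_MANT_MAX * 2^.BIAS_EXP_MAX)
    stop(sprintf("bias unrepresentable: |b| = %.4g > 4096 * 2^7", abs(b)),
         call. = FALSE)
  best <- NULL
  for (e in 0:.BIAS_EXP_MAX) {
    m <- floor(b / 2^e + 0.5)
    if (abs(m) > .BIAS_MANT_MAX) next  # mantissa out of range at this e
    err <- abs(m * 2^e - b)
    if (is.null(best) || err < best$err)
      best <- list(mantissa = as.integer(m), exponent = as.integer(e), err = err)
  }
  list(mantissa = best$mantissa, exponent = best$exponent,
       value = best$mantissa * 2^best$exponent)
}

#' Quantize a threshold onto the 17-high-bit grid
#'
#' The threshold register holds 17 bits interpreted as the high bits of a
#' 23-bit word, so representable thresholds are multiples of `2^6 = 64`.
#' Rounds to the nearest multiple of 64.
#'
#' @param theta_levels Threshold in levels, in `[0, 2^23)`.
#' @return Integer threshold, a multiple of 64.
#' @export
quantize_threshold <- function(theta_levels) {
  if (!is.finite(theta_levels) || theta_levels < 0 || theta_levels >= .STATE_MAX)
    stop(sprintf("threshold unrepresentable: %.4g outside [0, 2^23)",
                 theta_levels), call. = FALSE)
  step <- 2^.THETA_LOW_BITS
  as.integer(floor(theta_levels / step + 0.5) * step)
}

#' Map a synaptic weight to an integer level increment
#'
#' An afferent spike adds `w_syn` pA to the synaptic current; in hardware
#' units (levels of the per-step current state `u`) that is
#' `round(w_syn * dt / (c_m * v_s))` levels per spike.
#'
#' @param w_syn Synaptic weight (pA per spike).
#' @inheritParams compute_bias
#' @return Integer level increment per spike.
#' @export
map_weight <- function(w_syn, params, cfg) {
  if (!is.finite(w_syn)) stop("non-finite weight", call. = FALSE)
  w <- floor(w_syn * cfg$dt / (params$c_m * cfg$v_s) + 0.5)
  if (abs(w) >= .STATE_MAX)
    stop(sprintf("weight unrepresentable: |%g| levels >= 2^23", w), call. = FALSE)
  as.integer(w)
}

#' Map a physical-unit neuron onto the quantized hardware compartment
#'
#' Composes the individual quantizers: 12-bit voltage and current decays
#' from `tau_v` and `tau_syn`, the mantissa/exponent bias from `i_bias`
#' (plus the residual resting-vs-reset drive), the 17-high-bit threshold
#' from `theta`, and the integer synaptic weight from `w_syn`.
#'
#' @inheritParams compute_bias
#' @param clamp_decay Passed to [compute_decay()]; saturate out-of-range
#'   decays at 4096 instead of erroring.
#' @return An object of class `loihi_config` with fields `delta_v`,
#'   `delta_u`, `theta_hw`, `bias_mantissa`, `bias_exponent`, `bias`
#'   (encoded value), `w_hw`, `v0` (initial state, levels), plus the
#'   `params` and `cfg` used, for inverse mapping.
#' @export
#' @examples
#' map_neuron(example_neuron(1), mapping_config(v_s = 1e-4, dt = 1))
map_neuron <- function(params, cfg, clamp_decay = FALSE) {
  stopifnot(inherits(params, "lif_params"), inherits(cfg, "mapping_config"))
  ctx <- function(field, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", field, conditionMessage(e)), call. = FALSE))
  }
  dv <- ctx("delta_v (membrane decay)",
            compute_decay(params$tau_v, cfg$dt, clamp = clamp_decay))
  du <- ctx("delta_u (current decay)",
            compute_decay(params$tau_syn, cfg$dt, clamp = clamp_decay))
  bq <- ctx("bias", quantize_bias(compute_bias(params, cfg)))
  th <- ctx("theta_hw (threshold)",
            quantize_threshold(to_levels(params$theta, params$v_r, cfg$v_s)))
  w <- ctx("w_hw (synaptic weight)", map_weight(params$w_syn, params, cfg))
  v0 <- as.integer(floor(to_levels(params$e_l, params$v_r, cfg$v_s) + 0.5))
  structure(
    list(delta_v = dv$delta, delta_u = du$delta,
         decay_clamped = dv$clamped || du$clamped,
         theta_hw = th,
         bias_mantissa = bq$mantissa, bias_exponent = bq$exponent,
         bias = bq$value, w_hw = w, v0 = v0,
         params = params, cfg = cfg),
    class = "loihi_config")
}

#' @export
print.loihi_config <- function(x, ...) {
  cat("quantized hardware compartment config\n")
  cat(sprintf("  delta_v %5d /4096   delta_u %5d /4096%s\n",
              x$delta_v, x$delta_u,
              if (isTRUE(x$decay_clamped)) "   [decay clamped]" else ""))
  cat(sprintf("  theta_hw %d levels (= %d * 64)\n", x$theta_hw, x$theta_hw %/% 64L))
  cat(sprintf("  bias %d = %d * 2^%d levels/step\n",
              x$bias, x$bias_mantissa, x$bias_exponent))
  cat(sprintf("  w_hw %d levels/spike   v0 %d levels\n", x$w_hw, x$v0))
  cat(sprintf("  (mapped at v_s = %g mV/level, dt = %g ms/step)\n",
              x$cfg$v_s, x$cfg$dt))
  invisible(x)
}

#' Read / write a mapped hardware config as JSON
#'
#' Round-trippable serialization of a `loihi_config`, including the
#' physical parameters and precision configuration it was mapped from.
#'
#' @param cfg A `loihi_config` (for writing).
#' @param path File path.
#' @return `read_loihi_config()` returns a `loihi_config`.
#' @export
write_loihi_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "loihi_config"))
  out <- cfg
  out$params <- unclass(out$params)
  out$cfg <- unclass(out$cfg)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_loihi_config
#' @export
read_loihi_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  params <- do.call(lif_params, raw$params[c("c_m", "tau_v", "e_l", "v_r",
                                             "theta", "i_bias", "tau_syn",
                                             "w_syn")])
  mcfg <- mapping_config(v_s = raw$cfg$v_s, dt = raw$cfg$dt)
  cfg <- map_neuron(params, mcfg, clamp_decay = isTRUE(raw$decay_clamped))
  # serialized integers are authoritative
  for (f in c("delta_v", "delta_u", "theta_hw", "bias_mantissa",
              "bias_exponent", "bias", "w_hw", "v0"))
    cfg[[f]] <- if (f == "bias") raw[[f]] else as.integer(raw[[f]])
  cfg
}
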