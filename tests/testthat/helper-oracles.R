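# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Naive transcription of the hardware update rule using integer floor
# division (%/%), independent of decay_multiply()/run_emulator().
oracle_emulator <- function(delta_v, delta_u, bias, theta, inc, n_steps,
                            v0 = 0, apply_threshold = TRUE) {
  v <- v0; u <- 0
  vs <- numeric(n_steps); us <- numeric(n_steps); sp <- integer(0)
  for (k in seq_len(n_steps)) {
    u <- (u * (4096 - delta_u)) %/% 4096 + inc[k]
    v <- (v * (4096 - delta_v)) %/% 4096 + bias + u
    if (apply_threshold && v > theta) { sp <- c(sp, k); v <- 0 }
    vs[k] <- v; us[k] <- u
  }
  list(v = vs, u = us, spikes = sp)
}

# Closed-form membrane trajectory for constant bias, no synaptic input:
# V(t) = V_inf + (V0 - V_inf) exp(-t/tau), V_inf = e_l + r_m * i_bias.
oracle_closed_form <- function(params, times, v0 = params$e_l) {
  v_inf <- params$e_l + params$r_m * params$i_bias
  v_inf + (v0 - v_inf) * exp(-times / params$tau_v)
}

# Brute-force best mantissa/exponent encoding over the full grid.
oracle_bias_grid <- function(b) {
  best <- NULL
  for (e in 0:7) for (m in -4096:4096) {
    err <- abs(m * 2^e - b)
    if (is.null(best) || err < best$err - 1e-12)
      best <- list(m = m, e = e, err = err)
  }
  best
}
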