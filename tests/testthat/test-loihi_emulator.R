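test_that("decay multiply uses floor semantics on a 12-bit shift", {
  expect_equal(decay_multiply(4096, 164), 3932)
  expect_equal(decay_multiply(-1, 164), -1)
  expect_equal(decay_multiply(0, 500), 0)
  for (x in c(7, 123456, -99999)) expect_equal(decay_multiply(x, 4096), 0)
  set.seed(31)
  xs <- sample(-(2^23 - 1):(2^23 - 1), 200)
  ds <- sample(1:4096, 200, replace = TRUE)
  expect_equal(decay_multiply(xs, ds), (xs * (4096 - ds)) %/% 4096)
})

test_that("quiescent compartment stays at zero and never spikes", {
  p <- example_neuron(2)
  hw <- map_neuron(p, mapping_config())
  tr <- run_emulator(hw, n_steps = 200)
  expect_true(all(tr$v == 0))
  expect_true(all(tr$u == 0))
  expect_length(tr$spike_steps, 0)
})

test_that("bias-only fixed point matches the reference steady state", {
  hw <- map_neuron(example_neuron(1), mapping_config(v_s = 1e-4, dt = 1))
  expect_equal(hw$bias, 11752)
  expect_equal(hw$delta_v, 164L)
  # fixed point of v <- v(1 - delta/4096) + b is b*4096/delta
  fp <- hw$bias * 4096 / hw$delta_v
  expect_equal(from_levels(fp, -70, 1e-4), -40.65, tolerance = 1e-3)
  tr <- run_emulator(hw, n_steps = 1500, apply_threshold = FALSE)
  v_end <- from_levels(tail(tr$v, 1), -70, 1e-4)
  expect_equal(v_end, from_levels(fp, -70, 1e-4), tolerance = 1e-4)
  # cross-oracle: reference steady state is -40.63 mV, within 0.1 mV
  expect_lt(abs(v_end - (-70 + 200 * 25 / 170.21)), 0.1)
})

test_that("emulator matches the naive integer transcription step for step", {
  set.seed(41)
  for (i in 1:10) {
    p <- lif_params(c_m = runif(1, 80, 300), tau_v = runif(1, 2, 100),
                    e_l = -70, v_r = -70, theta = runif(1, -60, -20),
                    i_bias = runif(1, 0, 300), tau_syn = runif(1, 1.5, 20))
    hw <- map_neuron(p, mapping_config())
    n <- 1000
    inc <- numeric(n)
    ks <- sample(n, 20)
    inc[ks] <- sample(0:5000, 20, replace = TRUE)
    tr <- run_emulator(hw, stimulus = inc, n_steps = n)
    o <- oracle_emulator(hw$delta_v, hw$delta_u, hw$bias, hw$theta_hw,
                         inc, n, v0 = hw$v0)
    expect_identical(tr$v[-1], o$v)
    expect_identical(tr$u[-1], o$u)
    expect_identical(tr$spike_steps, o$spikes)
  }
})

test_that("spike scheduling rounds times to steps and sums coincidences", {
  sched <- schedule_spikes(c(53, 258, 300, 424, 457), dt = 1, n_steps = 500)
  expect_equal(which(sched > 0), c(53, 258, 300, 424, 457))
  expect_equal(schedule_spikes(446, dt = 10, n_steps = 50) |> which.max(), 45L)
  expect_equal(schedule_spikes(numeric(0), dt = 1, n_steps = 10),
               numeric(10))
  # coincident arrivals sum
  s <- schedule_spikes(c(100, 100.2), dt = 1, n_steps = 200,
                       increments = c(3, 4))
  expect_equal(s[100], 7)
  expect_error(schedule_spikes(600, dt = 1, n_steps = 500), "beyond")
})

test_that("unquantized mode reproduces forward Euler and converges as O(dt)", {
  p <- example_neuron(1)
  err <- sapply(c(1, 0.5, 0.25), function(dt) {
    cfg <- mapping_config(v_s = 1e-4, dt = dt)
    hw <- map_neuron(p, cfg)
    n <- round(200 / dt)
    tr <- run_emulator(hw, n_steps = n, apply_threshold = FALSE,
                       quantize = FALSE)
    # independent Euler recursion in physical units
    v_euler <- numeric(n); v <- -70
    b <- 200 / 170.21 * dt  # mV per step (e_l == v_r, no syn input)
    for (k in 1:n) { v <- v + dt * (-(v + 70) / 25) + b; v_euler[k] <- v }
    expect_equal(from_levels(tr$v[-1], -70, 1e-4), v_euler,
                 tolerance = 1e-12)
    # error against the exact solution at t = 200
    abs(v_euler[n] - oracle_closed_form(p, 200))
  })
  # halving dt roughly halves the error (first-order convergence)
  expect_gt(err[1] / err[2], 1.6)
  expect_gt(err[2] / err[3], 1.6)
})

test_that("reset and strict threshold: v is 0 on post-spike steps", {
  hw <- map_neuron(example_neuron(1), mapping_config())
  tr <- run_emulator(hw, n_steps = 500)
  expect_gt(length(tr$spike_steps), 3)
  expect_true(all(tr$v[tr$spike_steps + 1L] == 0))
  expect_true(all(tr$v <= hw$theta_hw))
  # exactly-at-threshold does not fire
  st <- list(v = hw$theta_hw, u = 0, t = 0L)
  cfg0 <- hw; cfg0$bias <- 0; cfg0$delta_v <- 4096L
  out <- emulator_step(list(v = 0, u = 0, t = 0L), cfg0,
                       spike_increment = hw$theta_hw)
  expect_false(out$spiked)  # v lands exactly on theta_hw
})

test_that("state overflow errors loudly, or saturates on request", {
  hw <- map_neuron(example_neuron(1), mapping_config())
  inc <- rep(2^22, 100)  # drives u toward 2^22/(delta_u/4096) > 2^23
  expect_error(run_emulator(hw, stimulus = inc, n_steps = 100,
                            apply_threshold = FALSE),
               "state overflow")
  tr <- run_emulator(hw, stimulus = inc, n_steps = 100,
                     apply_threshold = FALSE, saturate = TRUE)
  expect_true(all(abs(tr$v) < 2^23))
  expect_true(all(abs(tr$u) < 2^23))
})

test_that("emulator runs are deterministic", {
  hw <- map_neuron(example_neuron(2), mapping_config())
  stim <- frozen_spike_fixture(weight = 60)
  a <- run_emulator(hw, stim, n_steps = 500)
  b <- run_emulator(hw, stim, n_steps = 500)
  expect_identical(a$v, b$v)
  expect_identical(a$u, b$u)
})

test_that("one-step synaptic delivery in a two-neuron chain", {
  p <- example_neuron(1)  # bias-driven, spikes regularly
  q <- example_neuron(2)
  cfg <- mapping_config()
  spec <- network_spec(list(map_neuron(p, cfg), map_neuron(q, cfg)),
                       edges = data.frame(pre = 1, post = 2, weight = 5000))
  run <- run_network(spec, 200)
  expect_gt(length(run$spike_steps[[1]]), 0)
  t1 <- run$spike_steps[[1]][1]
  # postsynaptic current state jumps exactly one step after the spike
  expect_equal(run$u[t1 + 1L, 2], 0)       # row t1+1 is step t1
  expect_equal(run$u[t1 + 2L, 2], 5000)    # delivered at step t1+1
})

test_that("an unconnected network equals independent single runs", {
  cfg <- mapping_config()
  hws <- list(map_neuron(example_neuron(1), cfg),
              map_neuron(example_neuron(2), cfg),
              map_neuron(example_neuron(1, i_bias = 150), cfg))
  spec <- network_spec(hws)
  run <- run_network(spec, 300)
  for (j in 1:3) {
    single <- run_emulator(hws[[j]], n_steps = 300)
    expect_identical(network_trace(run, j)$v, single$v)
    expect_identical(network_trace(run, j)$spike_steps,
                     as.integer(single$spike_steps))
  }
})
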