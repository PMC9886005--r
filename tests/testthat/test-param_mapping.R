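test_that("voltage transforms match their definitions and invert exactly", {
  expect_equal(to_levels(-70, -70, 1e-4), 0)
  expect_equal(to_levels(-43, -70, 1e-4), 270000)
  expect_equal(from_levels(0, -70, 1e-4), -70)
  expect_equal(from_levels(270000, -70, 1e-4), -43)

  set.seed(42)
  v <- runif(100, -120, 40)
  for (v_s in c(1e-3, 1e-4, 1e-5)) {
    expect_equal(from_levels(to_levels(v, -70, v_s), -70, v_s), v,
                 tolerance = 1e-12)
  }
  expect_error(to_levels(NaN, -70, 1e-4), "non-finite")
  expect_error(from_levels(Inf, -70, 1e-4), "non-finite")
})

test_that("decay quantization follows (dt/tau)*2^12 with nearest rounding", {
  d <- compute_decay(25, 1)
  expect_equal(d$raw, 163.84)
  expect_equal(d$delta, 164L)
  # boundary of the representable range
  d <- compute_decay(4096 * 0.5, 0.5)
  expect_equal(d$raw, 1)
  expect_equal(d$delta, 1L)
  # full decay at tau == dt
  expect_equal(compute_decay(1, 1)$delta, 4096L)
  expect_error(compute_decay(50, 0.01), "unrepresentable")
  expect_error(compute_decay(0.5, 1), "decay overflow")
  # clamp mode saturates instead
  expect_equal(compute_decay(0.5, 1, clamp = TRUE)$delta, 4096L)
})

test_that("representability window is dt <= tau <= 4096*dt", {
  expect_equal(max_representable_tau(0.01), 40.96)
  expect_equal(max_representable_tau(1), 4096)
  # both worked parameter sets map without error at dt = 1
  for (s in 1:2)
    expect_s3_class(map_neuron(example_neuron(s), mapping_config()),
                    "loihi_config")
})

test_that("decay identity holds to half a quantization step", {
  set.seed(7)
  for (tau in runif(20, 1.5, 400)) {
    delta <- compute_decay(tau, 1)$delta
    expect_lt(abs((4096 - delta) / 4096 - (1 - 1 / tau)), 1 / 8192)
  }
})

test_that("bias computation matches hand arithmetic and scales with 1/v_s", {
  p <- example_neuron(1)
  cfg <- mapping_config(v_s = 1e-4, dt = 1)
  b <- compute_bias(p, cfg)
  expect_equal(b, 200 / (170.21 * 1e-4), tolerance = 1e-12)
  # e_l == v_r and zero current force zero bias
  expect_equal(compute_bias(example_neuron(2), cfg), 0)
  # doubling v_s halves b
  expect_equal(compute_bias(p, mapping_config(v_s = 2e-4, dt = 1)), b / 2,
               tolerance = 1e-12)
  # the residual (e_l - v_r)/tau_v drive is included when e_l != v_r
  p2 <- lif_params(c_m = 100, tau_v = 20, e_l = -65, v_r = -70,
                   theta = -40, i_bias = 0)
  expect_equal(compute_bias(p2, cfg), (5 / 20) / 1e-4, tolerance = 1e-12)
})

test_that("bias mantissa/exponent encoding is grid-optimal with smallest-e ties", {
  expect_equal(quantize_bias(0)[c("mantissa", "exponent")],
               list(mantissa = 0L, exponent = 0L))
  q <- quantize_bias(11750.2)
  expect_equal(q$mantissa, 2938L)
  expect_equal(q$exponent, 2L)
  expect_equal(q$value, 11752)

  set.seed(11)
  for (b in c(runif(6, -4096 * 128, 4096 * 128), 4096 * 128, -3, 4097)) {
    q <- quantize_bias(b)
    o <- oracle_bias_grid(b)
    expect_equal(abs(q$value - b), o$err, tolerance = 1e-9)
    # encoding error is bounded by half the granularity at the chosen e
    expect_lte(abs(q$value - b), 2^q$exponent / 2)
  }
  expect_error(quantize_bias(4096 * 128 + 1), "bias unrepresentable")
})

test_that("threshold quantizer rounds to the nearest multiple of 64", {
  expect_equal(quantize_threshold(0), 0L)
  expect_equal(quantize_threshold(270000), 270016L)
  expect_equal(270016 %% 64, 0)
  set.seed(3)
  for (x in runif(50, 0, 2^23 - 1)) {
    q <- quantize_threshold(x)
    expect_equal(q %% 64, 0)
    expect_lte(abs(q - x), 32)
  }
  expect_error(quantize_threshold(-1), "unrepresentable")
  expect_error(quantize_threshold(2^23), "unrepresentable")
})

test_that("synaptic weight mapping is the rounded level increment", {
  cfg <- mapping_config(v_s = 1e-4, dt = 1)
  p <- lif_params(c_m = 170, tau_v = 25, e_l = -70, v_r = -70, theta = -43)
  expect_equal(map_weight(0, p, cfg), 0L)
  expect_equal(map_weight(100, p, cfg), 5882L)
  # linear up to rounding by <= 1
  set.seed(5)
  for (w in runif(20, -500, 500))
    expect_lte(abs(map_weight(2 * w, p, cfg) - 2 * map_weight(w, p, cfg)), 1)
})

test_that("map_neuron composes the quantizers and inverts tau within one step", {
  cfg <- mapping_config(v_s = 1e-4, dt = 1)
  hw <- map_neuron(example_neuron(1), cfg)
  expect_equal(hw$delta_v, 164L)
  expect_equal(hw$theta_hw, 270016L)
  expect_equal(hw$bias_mantissa, 2938L)
  expect_equal(hw$bias_exponent, 2L)

  hw2 <- map_neuron(example_neuron(2), cfg)
  expect_equal(hw2$delta_v, 186L)
  expect_equal(hw2$bias, 0)

  # mapped-then-inverted tau within one quantization step
  set.seed(9)
  for (tau in runif(20, 2, 3000)) {
    delta <- compute_decay(tau, 1)$delta
    tau_back <- 4096 * 1 / delta
    tau_lo <- 4096 / (delta + 0.5); tau_hi <- 4096 / (delta - 0.5)
    expect_gte(tau, tau_lo); expect_lte(tau, tau_hi)
    expect_lt(abs(tau_back - tau), 4096 / (delta - 0.5) - 4096 / (delta + 0.5))
  }

  # errors name the offending field
  expect_error(map_neuron(example_neuron(1, tau_v = 50),
                          mapping_config(dt = 0.01)),
               "delta_v.*unrepresentable")
})

test_that("all quantizers are idempotent", {
  set.seed(13)
  for (x in runif(20, 0, 2^23 - 64))
    expect_equal(quantize_threshold(quantize_threshold(x)),
                 quantize_threshold(x))
  for (b in runif(20, -4096 * 100, 4096 * 100)) {
    q <- quantize_bias(b)
    expect_equal(quantize_bias(q$value)$value, q$value)
  }
  for (tau in runif(20, 2, 3000)) {
    delta <- compute_decay(tau, 1)$delta
    expect_equal(compute_decay(4096 / delta, 1)$delta, delta)
  }
})

test_that("parameter and config files round-trip", {
  p <- example_neuron(1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_lif_params(list(p, example_neuron(2)), f)
  back <- read_lif_params(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$c_m, p$c_m)
  expect_equal(back[[1]]$w_syn, p$w_syn)

  hw <- map_neuron(p, mapping_config())
  g <- withr::local_tempfile(fileext = ".json")
  write_loihi_config(hw, g)
  hw2 <- read_loihi_config(g)
  for (field in c("delta_v", "delta_u", "theta_hw", "bias_mantissa",
                  "bias_exponent", "bias", "w_hw", "v0"))
    expect_equal(hw2[[field]], hw[[field]], info = field)

  # a mapped config is rejected as physical-parameter input
  write_lif_params(p, f)
  df <- utils::read.csv(f); df$delta_v <- 164
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_lif_params(f), "already-mapped")
})
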