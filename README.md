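# lifmap

Map leaky integrate-and-fire (LIF) point neurons from physical units onto a
fixed-point neuromorphic compartment model — and measure exactly how much
fidelity the quantization costs.

Digital neuromorphic chips implement LIF dynamics as a discrete-time,
discrete-state update on narrow integer registers: membrane potential and
synaptic current in ±23-bit words, per-step decays in a 12-bit constant,
thresholds on a 64-level grid, and the input bias as a mantissa/exponent
pair. A modeller working from electrophysiology databases has parameters in
mV, ms, pA and pF. `lifmap` is for computational neuroscientists who need to
move models between those two worlds and certify the result: it performs the
forward translation, emulates the hardware arithmetic bit-for-bit, simulates
the continuous model with an exact integrator as ground truth, and
quantifies the agreement.

## The model and the mapping

The continuous neuron is the classical LIF model

```
V'(t) = [I_e(t) - (V(t) - E_L)/R] / C,    V(t) <- V_r  if  V(t) > Θ
```

with membrane time constant τ_v = RC, driven by a constant bias current
and/or exponential postsynaptic currents (I_syn' = -I_syn/τ_syn, jumping by
w per afferent spike). The reference simulator advances the two-state linear
system with its exact matrix-exponential propagator on a fixed grid, so
on-grid values carry no integration error at any step size.

The hardware compartment evolves two integer states by

```
u(t+1) = u(t) * (2^12 - δ_u)/2^12 + Σ (weights of arriving spikes)
v(t+1) = v(t) * (2^12 - δ_v)/2^12 + b + u(t+1),    v <- 0  if  v > θ
```

with floor rounding after every decay multiply. Choosing a voltage scale
V_s (mV per level) and a temporal scale dt (ms per step), the translation is

- voltage transform: `v = (V - V_r)/V_s` (so the hardware reset 0 is the
  physical reset V_r), inverse `V = v·V_s + V_r`;
- decays: `δ = (dt/τ)·2^12`, rounded to the nearest integer in [1, 4096] —
  representable time constants therefore satisfy dt ≤ τ ≤ 4096·dt;
- threshold: `θ = (Θ - V_r)/V_s`, rounded to the nearest multiple of 64;
- bias: `b = [I/(C·V_s) + (E_L - V_r)/(τ_v·V_s)]·dt`, encoded as m·2^e with
  m ∈ [-4096, 4096], e ∈ [0, 7], minimizing the encoding error;
- synaptic weights: `round(w·dt/(C·V_s))` levels per spike.

Validation inverse-maps the emulator trace to mV and reports RMSE and the
Pearson correlation against the reference, plus density/raster/scatter
diagnostics.

## Worked example

A mouse-cortex neuron (τ_v = 25 ms, C = 170.21 pF, rest/reset −70 mV,
threshold −43 mV) driven by a 200 pA bias, mapped at dt = 1 ms/step and
V_s = 1e-4 mV/level:

```r
library(lifmap)
p   <- example_neuron(1)
cfg <- mapping_config(v_s = 1e-4, dt = 1)
map_neuron(p, cfg)
#> quantized hardware compartment config
#>   delta_v   164 /4096   delta_u   819 /4096
#>   theta_hw 270016 levels (= 4219 * 64)
#>   bias 11752 = 2938 * 2^2 levels/step
#>   w_hw 2991 levels/spike   v0 0 levels
#>   (mapped at v_s = 0.0001 mV/level, dt = 1 ms/step)
```

δ_v = 164 is (1/25)·4096 rounded; the −43 mV threshold lands on the 64-level
grid at 270,016; the per-step bias 11,752 levels encodes 200 pA as
2938·2^2. Running both backends for 500 ms and comparing after inverse
mapping:

```r
run_single_neuron(p, NULL, cfg)
#> cross-backend comparison report
#>   membrane potential: RMSE 0.06558 mV, r = 0.999943 (n = 500)
#>   synaptic current:   RMSE 0 pA, r = NA
#>   spikes: reference 0, emulator 0

run_single_neuron(example_neuron(2), frozen_spike_fixture(), cfg)
#> cross-backend comparison report
#>   membrane potential: RMSE 0.02893 mV, r = 0.999071 (n = 500)
#>   synaptic current:   RMSE 1.042 pA, r = 0.998495
#>   spikes: reference 0, emulator 0
```

The sub-0.1 mV RMSE and r > 0.999 say the 23-bit/12-bit compartment tracks
the exact continuous solution to within a tenth of a millivolt over the
whole run; the residual is the Euler-style time discretization plus the
decay quantization, not a modelling difference. (The current correlation is
undefined in the bias-only run because both series are constant zero.)

Precision sweeps (`sweep_dt()`, `sweep_vs()`) show the same trade-offs a
hardware user faces: error is minimized at dt = 1 ms/step — finer steps
shrink the 12-bit decay and coarser steps overrun τ_syn — and finer voltage
scales help the membrane potential until quantization is no longer the
bottleneck. `run_ensemble()` validates a whole table of neuron classes,
`build_random_network()`/`run_network()` scale to random
excitatory/inhibitory networks, and `inst/cli/lifmap` exposes the pipeline
as `map`, `simulate`, `validate`, `sweep-dt`, `sweep-vs`, `ensemble`,
`network` and `scaling` subcommands.

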