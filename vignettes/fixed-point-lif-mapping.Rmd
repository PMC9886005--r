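---
title: "Mapping LIF neurons onto a fixed-point neuromorphic compartment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping LIF neurons onto a fixed-point neuromorphic compartment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifmap)
```

## The problem

Digital neuromorphic hardware trades floating-point generality for
massively parallel integer arithmetic. A compartment holds its membrane
potential `v` and synaptic current `u` in ±23-bit registers, decays them
once per algorithmic time step by multiplying with `(2^12 - δ)/2^12`
(δ a 12-bit constant, 0 encoding 4096), adds a bias encoded as
mantissa·2^exponent, and fires when `v` strictly exceeds a threshold
stored as the 17 high bits of a 23-bit word. None of these quantities has
physical units.

A modeller, by contrast, specifies a leaky integrate-and-fire neuron in
the units of the electrophysiology literature:

$$ V'(t) = \frac{1}{C}\Big[I_e(t) - \frac{V(t)-E_L}{R}\Big], \qquad
   V \leftarrow V_r \text{ if } V > \Theta, $$

with τ_v = RC in ms, potentials in mV, currents in pA and capacitance in
pF. This package implements the translation between the two
representations and, more importantly, the machinery to certify it: a
ground-truth simulator of the continuous model, a bit-faithful emulator of
the integer update, and metrics comparing the two after mapping the
emulator's states back to physical units.

## The mapping

With a voltage scale `v_s` (mV per level) and a temporal scale `dt` (ms
per step) the transforms are

* `to_levels()`: `v = (V - V_r)/v_s`, placing the physical reset at the
  hardware reset 0; `from_levels()` inverts it exactly.
* `compute_decay()`: equating the hardware decay factor `1 - δ/4096` with
  the Euler factor `1 - dt/τ` gives `δ = (dt/τ)·2^12`. The 12-bit register
  restricts representable time constants to `dt ≤ τ ≤ 4096·dt`; at
  `dt = 0.01` ms/step that already caps τ_v at 40.96 ms.
* `compute_bias()`: the per-step drive
  `b = [I/(C·v_s) + (E_L - V_r)/(τ_v·v_s)]·dt`. The second term is the
  residual reference drive when rest and reset differ; it is folded into
  the bias because the hardware has no separate register for it (it
  vanishes for the worked parameter sets, where `E_L = V_r`).
* `quantize_bias()`: exhaustive minimization of `|m·2^e - b|` over
  `m ∈ [-4096, 4096]`, `e ∈ [0, 7]`, ties to the smallest exponent.
  Exponents whose mantissa would leave the register range are skipped, so
  the encoding error is always at most `2^(e-1)`.
* `quantize_threshold()`: nearest multiple of 64 (the 17-high-bit grid).
* `map_weight()`: an afferent spike that adds `w` pA to the synaptic
  current adds `round(w·dt/(C·v_s))` levels to `u`.

All quantizers round to nearest and are idempotent. `map_neuron()`
composes them and reports the offending field when a constraint bites.

## The two simulators

**Reference (exact integration).** Subthreshold, the model is the linear
system `V' = -(V - E_L - R·I_bias)/τ_v + I_syn/C`,
`I_syn' = -I_syn/τ_syn`. Its per-step propagator is the matrix exponential
of a triangular 2×2 system and has a closed form
(`exp(-h/τ_v)`, `exp(-h/τ_syn)`, and a coupling coefficient); on-grid
values are exact for any step `h`, which is what distinguishes this scheme
from forward Euler and makes the reference a legitimate ground truth. When
`τ_syn = τ_v` the analytic alpha-function limit `p_vi = (h/C)·e^{-h/τ}` is
used rather than a perturbation, so the degenerate case is exact too.
There is no refractory period in the model.

**Emulator (fixed-point).** `run_emulator()` executes the integer
recursion exactly as the hardware does: decay-multiply with floor
rounding (arithmetic right shift — the hardware-natural choice; the update
rule itself does not dictate a rounding direction), current before
voltage so the freshly updated `u` enters `v` in the same step, strict
threshold test, reset to 0, and a 23-bit range check after every update.
Overflow is an error by default — silent wraparound would invalidate any
comparison — with an opt-in saturation mode for large-network scaling
runs. With `quantize = FALSE` the same recursion runs on real-valued
states with unrounded decays, which is precisely forward-Euler
integration; the suite uses this to separate time-discretization error
from quantization error and to verify O(dt) convergence.

**Event alignment.** An input spike at time `t` affects the reference
step ending at the first grid point ≥ `t`, with the current injected at
the start of that step; the emulator schedules it at step `round(t/dt)`,
where it enters `u` and hence `v` within the same step. Both backends
thus treat the event as acting over the step that ends at its delivery
point, and the recorded reference current is the post-delivery value —
the quantity the hardware `u` state represents. A consequence of on-grid
delivery is that refining `h` moves injection instants (they are tied to
the grid), so the grid-refinement invariance of the integrator is exact
for constant-bias input and only approximate across spike stimuli.
Spike-to-spike synaptic delivery in networks has a fixed one-step latency
(synchronous two-phase update).

## Stimuli and study conditions

The package ships the frozen five-source, eleven-event spike fixture used
by the worked single-neuron validation (`frozen_spike_fixture()`), and a
seeded homogeneous Poisson generator (`poisson_spike_trains()`; the
"maximum rate 5 Hz" of the original stimulus protocol is implemented as a
constant 5 Hz rate, there being no stated modulation). Defaults follow the
worked studies: 500 ms runs, `dt = 1` ms/step, `v_s = 1e-4` mV/level
(10,000 levels per mV, the middle of the voltage-precision sweep),
`τ_syn = 5` ms, and a synaptic weight sized by `psp_weight()` so a single
spike peaks at ~1 mV — the stimulus protocol's weight is not printed, so
the package documents its own default and exposes it.

The synthetic ensemble generator (`synthetic_neuron_classes()`) emulates a
catalogue of cortical cell classes: half excitatory, half inhibitory,
τ_v uniform on [10, 50] ms, C on [80, 300] pF, bias on [50, 250] pA, with
shared rest/reset/threshold. It reproduces the *spread* of catalogued
parameters, not any measured cell, and is labelled synthetic throughout.
Likewise the random-network builder draws Erdős–Rényi connectivity at
p = 0.1 with a 1:1 excitatory:inhibitory split and bias drive. What
passing tests on these inputs shows is that the mapping and emulator are
correct under realistic parameter ranges; they say nothing about
biological adequacy of the LIF model itself, about measured cell
parameters, or about behaviour under stimuli richer than bias currents
and Poisson trains.

## Threshold regime for validation runs

The worked bias-current neuron maps to a steady state (−40.65 mV) slightly
above its −43 mV threshold. With threshold and reset active the two
backends disagree on the firing period by one step (62 vs 63), because
the emulator's Euler-style decay is slightly faster than the exact decay
(effective τ 24.47 ms vs 25 ms); the resulting phase drift dominates any
sample-wise comparison and says nothing about the mapping itself. The
single-neuron validation experiments are therefore defined on the free
subthreshold trajectory (`regime = "subthreshold"`, the default in
`run_single_neuron()`), which is also how the original single-neuron
studies are framed; the spiking regime is fully implemented and reported
separately (`regime = "spiking"`), and spike counts from both backends
appear in every report.

## Validation metrics and diagnostics

`align_traces()` inverse-maps the emulator (voltage via `from_levels()`,
current via `u·C·v_s/dt`) and samples the reference on the emulator grid,
excluding the shared initial state: a 500 ms run at `dt = 1` compares 500
pairs; at `dt = 10` against an `h = 1` reference it compares every tenth
point, 50 pairs. `trace_rmse()` and `trace_pearson()` implement the two
cost functions (RMSE in mV; the correlation is affine-invariant, so it is
identical on raw levels). RMSE is computed over all time points; a
comparison restricted to the subthreshold regime avoids the question of
masking reset transients. `trace_diagnostics()` returns the three
plot-ready summaries — per-series Gaussian-kernel densities (Silverman
bandwidth), value-vs-time raster arrays, and the scatter pairing with its
least-squares trend line.

## Precision sweeps

`sweep_dt()` re-maps and re-runs a neuron at `dt ∈ {0.1, 1, 10}` ms/step
(fixed `v_s`), with the reference on the finer of 1 ms and `dt` and the
comparison on the emulator grid. The error is U-shaped in `dt`: finer
steps shrink δ toward 1 and make its rounding relatively coarser (at
`dt = 0.1`, δ_v = 16 carries a 2.4% time-constant error versus 0.1% at
`dt = 1`), while `dt = 10` exceeds τ_syn = 5 ms, where the 12-bit decay
saturates at complete-decay-per-step (`compute_decay(clamp = TRUE)`; the
sweep flags such rows) and the simulation degrades badly. `sweep_vs()`
varies `v_s ∈ {1e-3, 1e-4, 1e-5}` at `dt = 1`: the membrane-potential
error improves markedly from 1e-3 to 1e-4 and the current error is
already quantization-saturated at 1e-4. Rows that fail to map at some
precision are flagged per row, not fatal.

## Numerical choices and edge cases

* Decay, threshold, weight and initial-state rounding: nearest, half away
  from zero. Bias encoding: grid-optimal with smallest-exponent ties.
* Strict inequalities at both thresholds (`v > θ`); a state exactly at
  threshold does not fire.
* Integer states are held in doubles; every intermediate (≤ 35 bits) is
  far inside the 53-bit exact-integer range, so the arithmetic is
  bit-exact, which the suite verifies against an independent
  floor-division transcription of the update rule.
* Degenerate inputs: zero-rate Poisson specs give empty trains; empty
  spike schedules are all-zero; `E_L = V_r` with zero bias forces `b = 0`
  and an exactly flat trace (RMSE 0); correlation on a constant series is
  reported as `NA` rather than a number.
* Scaling runs (`scaling_study()`) report wall-clock times for connected
  vs unconnected networks; they are informational and host-dependent by
  construction. Default experiment sizes (500 ms single neurons, 20-class
  ensembles, tens-of-neurons networks) keep the full suite in the
  tens-of-seconds range.

## Known limitations

* The emulator models a single compartment type: no dendritic trees,
  learning engine, axonal delays beyond the fixed one-step synaptic
  latency, or mantissa/exponent weight compression.
* The reference simulator covers current-based exponential synapses only
  — the synapse model implied by the exponential postsynaptic currents of
  the original setup — not conductance-based or alpha synapses (except as
  the τ_syn = τ_v limit).
* File interfaces are plain text (CSV/JSON/YAML).
* Network-level validation is structural (determinism, independence,
  delivery latency, edge statistics); sample-wise cross-simulator network
  comparison is out of scope, as subthreshold network states are not
  expected to replicate across simulators except in trivial cases.
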