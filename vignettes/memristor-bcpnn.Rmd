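---
title: "Emulating BCPNN synaptic traces with threshold-type memristors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating BCPNN synaptic traces with threshold-type memristors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membcpnn)
```

## The model

The BCPNN (Bayesian Confidence Propagation Neural Network) learning rule
estimates firing and co-firing probabilities of pre- and post-synaptic
units through a cascade of exponential running averages. In discrete
time with step $dt$, binary spikes $S_i, S_j \in \{0,1\}$ drive the
Z traces

$$Z_i(t) = Z_i(t-1)\,(1 - k_z) + S_i(t-1)\,k_z,$$

which in the simplified rule (the variant this package emulates in
hardware terms; the full variant with the intermediate E "eligibility"
stage is available in `run_reference(variant = "full_E")` as a
reference) feed the slower P traces

$$P_i(t) = P_i(t-1)\,(1 - k_p) + Z_i(t-1)\,k_p,$$

with the mutual trace $P_{ij}$ driven by the product $Z_i Z_j$. The
smoothing constants are $k = dt/\tau$ per stage (with the learning-rate
modulation $\kappa$ folded into $k_p$). The P traces produce the
synaptic weight and unit bias in log space,

$$w_{ij} = \log(P_{ij} + \varepsilon^2) - \log(P_i + \varepsilon) -
  \log(P_j + \varepsilon), \qquad \beta_j = \log(P_j + \varepsilon),$$

where $\varepsilon$ is a minimum-activity floor. Note the *squared*
floor on the mutual term: it makes $w_{ij} = 0$ the exact fixed point
of a silent network, and all logs are natural logs (the silent fixed
point is base-independent; natural log is the convention in the BCPNN
literature). Correlated activity drives $w_{ij}$ positive,
anti-correlated activity negative.

The memristor side is a VTEAM (voltage-controlled threshold) device:
the internal state $w \in [0, W]$ (nm; $x = w/W$) is frozen inside the
dead zone $v_{on} < v < v_{off}$ and drifts as

$$\frac{dw}{dt} = k_{off}\Big(\frac{v}{v_{off}} - 1\Big)^{\alpha_{off}}
  f(x) \quad (v \ge v_{off}), \qquad
  \frac{dw}{dt} = k_{on}\Big(\frac{v}{v_{on}} - 1\Big)^{\alpha_{on}}
  f(x) \quad (v \le v_{on}),$$

with the nonlinear dopant-drift window $f(x) = j(1-x)^p$ for positive
current and $j x^p$ for negative. Resistance is affine in the state,
$R = R_{on} + (R_{off} - R_{on})x$.

## Why the mapping is exact

With the affine window ($j = p = 1$) and one forward-Euler step of
duration $t$, a positive pulse gives $w' = C w + D$ with
$C = 1 - t k_{off}(v/v_{off}-1)/W$, $D = t k_{off}(v/v_{off}-1)$, and a
negative pulse gives $w' = E w$ with
$E = 1 + t k_{on}(v/v_{on}-1)/W$. These are exactly the two branches of
the Z-trace recursion ($Z' = (1-k_z)Z + k_z$ on a spike,
$Z' = (1-k_z)Z$ on silence). `solve_drive_voltage()` inverts the
coefficients in closed form; for the default device, $k_z = 1/11$ and a
0.5 ms drive phase this yields 193.2 mV (excitatory) and −149.9 mV
(inhibitory):

```{r}
round(solve_drive_voltage(1 / 11, "excitatory", 5e-4) * 1000, 1)
round(solve_drive_voltage(1 / 11, "inhibitory", 5e-4) * 1000, 1)
```

A device pulsed with these voltages therefore tracks the Z trace to
machine precision on *any* binary train (`certify_z_exactness()`).

## The synapse architecture

`synapse_unit()` assembles the five-device synapse: devices for $Z_i$,
$Z_j$, $P_i$, $P_j$, $P_{ij}$, each behind a behavioral sample-and-hold
circuit. Every timestep has two phases. In the sampling phase a 50 nA
read current converts each resistance into a held voltage (the default
keeps $i_{read} R_{off} = 10$ mV below the 20 mV threshold, so reads
are non-destructive); the multiplier (an idealized Gilbert cell with
configurable gain/offset) forms $Z_i Z_j$ from the held Z values. In
the drive phase the Z devices receive the spike-selected calibrated
voltage, and each P device is driven toward its held target. The
weight and bias are computed from held P samples by idealized
logarithmic blocks. Because drives consume values sampled at the start
of the step, the one-step delay of the discrete rule is reproduced
structurally; recorded series are the held (observable) values, the
quantity an actual circuit could report.

### Driving a P stage

The rule's P update, $P' = (1-k_p)P + k_p\,\text{target}$, mixes decay
and growth in one step, but a single voltage pulse can only move the
state one way. The default `exact_dual_pulse` mode splits the 0.5 ms
drive phase into two 0.25 ms sub-pulses: a depressing pulse with rate
$d = k_p(1-\text{target})/(1 - k_p\,\text{target})$ followed by a
potentiating pulse with rate $g = k_p\,\text{target}$, each solved by
the same closed-form calibration. Since $(1-d)(1-g) = 1-k_p$, the
composite update equals the P step identically — this is the unique
two-pulse decomposition with that property, and it makes the whole
emulated cascade (P traces, weight, bias) agree with the reference to
rounding error (~1e−13 over 5000 steps).

An alternative `single_drive` mode applies one pulse whose voltage is
affine in the target, interpolating between the two solved $k_p$
voltages — the closest behavioral reading of a circuit that feeds the
held voltage straight to the device. Because the solved P-stage
voltages sit barely above the thresholds, the interpolated voltage
falls inside the dead zone for most intermediate targets and the P
devices hardly move; the harness quantifies this (correlations are
poor), which is why the mode exists for inspection but is not the
default and no fidelity is asserted for it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `kz_i`, `kz_j` | 1/11 | Z smoothing ($\tau_z = 11$ ms at $dt = 1$ ms) |
| `kp` | 1/500 | P smoothing ($\tau_p = 0.5$ s) |
| `eps` | 0.01 | activity floor; sets $\beta_j = \log\varepsilon$ at silence |
| `dt` | 1 ms | simulation step |
| `ke` | 1/100 | E smoothing, reference-only (no printed value exists for it; $\tau_e = 100$ ms is a typical eligibility time constant) |
| `v_on`/`v_off` | ∓20 mV | device thresholds |
| `r_on`/`r_off` | 2/200 kΩ | resistance range |
| `k_on`/`k_off` | −28/21 nm/s | drift-rate constants |
| `drive_fraction` | 0.5 | share of $dt$ spent driving |
| `i_read` | 50 nA | read current (sub-threshold) |
| `v_max` | 1 V | calibration reachability budget |

`drive_fraction = 0.5` deserves a note: only the product of pulse
duration and drift rate is identifiable from a target smoothing
constant, but 0.5 is the unique split under which the default device
reproduces *both* design voltages above simultaneously, so it is fixed
as the package default and kept configurable.

## Synthetic scenarios and what they (do not) show

`gen_dense()` draws independent Bernoulli($r\,dt$) spikes per channel
— the default 20 Hz at 1 ms bins emulates sustained dense activity.
`gen_overlap()`/`gen_separated()` produce 50 Hz bursts in coincident or
disjoint 1 s windows followed by ~10 s of silence, the regimes in which
the weight visibly potentiates then relaxes to zero, or dips negative
then recovers. The standard problem sizes used throughout the tests
are 5 s (5000 steps) for dense runs and 11 s for the decay scenario.

These generators emulate spike *statistics* only. They do not model
device-to-device or cycle-to-cycle variation, noise in the analog
chain, finite op-amp gain or multiplier distortion, or temperature —
so a passing comparison certifies the algebraic mapping and its
behavioral circuit schedule, not robustness of physical hardware.
Gain/offset imperfections can be injected through `readout_chain()` to
explore sensitivity.

## Numerical choices and degenerate inputs

* Integration is forward Euler with configurable substeps (default 1:
  the single-step update *is* the trace recursion; the exactness
  identities hold only there). Sub-`1e-12` overshoot of $[0, W]$ is
  clamped; larger overshoot raises an error suggesting more substeps.
* The window's current-sign argument is taken from the voltage branch
  (voltage and current share sign through a positive resistance),
  avoiding the need for an instantaneous current before the state
  update; at exactly $v = v_{off}$ or $v_{on}$ the polynomial factor is
  zero so the branch assignment is immaterial.
* `solve_drive_voltage(0, ...)` returns the threshold voltage with a
  warning (zero drift); targets whose solution exceeds `v_max` (1 V
  default, the sub-volt regime of the devices modeled) raise an
  unreachable-rate error. `k = 1` would require a full reset in one
  pulse and is rejected the same way.
* Pearson correlation of two identical non-constant series is reported
  as exactly 1; two constant series correlate 1 if equal and `NaN`
  (with a warning) otherwise.
* All traces start at 0 (matching the device's `w_init = 0`), so the
  silent network sits exactly at $w_{ij} = 0$,
  $\beta_j = \log\varepsilon$.

## Worked comparison

```{r}
sc <- gen_dense(duration = 1, rate = 20, seed = 42)
ref <- run_reference(sc$s_i, sc$s_j)
emu <- run_emulation(sc$s_i, sc$s_j)
as.data.frame(compare_traces(ref, emu))
```

The Z rows are zero to machine precision (the exactness theorem); the
P, weight and bias rows differ only by accumulated double rounding of
the per-step solved voltages.

## Known limitations

* Transistor-level behavior (SPICE timescales, Gilbert-cell bias
  points, op-amp and triode internals) is out of scope; the multiplier
  and log blocks are behavioral with ideal defaults.
* Calibration requires the affine window regime ($j = p = 1$); other
  windows are simulated by the device model but cannot be calibrated
  in closed form.
* The E-trace stage is reference-only; the hardware cascade omits it
  (it could be added as one more sample-and-hold level).
* No device variation or aging: identical pulses always produce
  identical updates.
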