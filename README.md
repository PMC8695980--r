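# membcpnn

Simulation toolkit for mapping the **BCPNN** (Bayesian Confidence
Propagation Neural Network) synaptic learning rule onto **memristive
devices**. It is aimed at neuromorphic-hardware researchers who want to
study, before committing to circuit design, whether an analog
in-memory synapse can carry the Bayesian-Hebbian trace cascade.

## The idea

BCPNN estimates firing and co-firing probabilities with cascaded
exponential running averages. Per 1 ms step, binary spikes drive the
fast Z traces,

```
Z(t) = Z(t-1)·(1 − kz) + S(t-1)·kz
```

which feed the slow P traces (`P' = P(1−kp) + kp·driver`, the driver
being `Z` or `Z_i·Z_j`), and the P traces give the log-odds weight and
bias

```
w_ij = log(P_ij + ε²) − log(P_i + ε) − log(P_j + ε),   β_j = log(P_j + ε).
```

A threshold-type (VTEAM) memristor with an affine dopant-drift window
obeys, per single Euler step under a constant pulse, exactly the same
affine recursion: `w' = C·w + D` for a potentiating pulse, `w' = E·w`
for a depressing one. The package solves, in closed form, the drive
voltages that make `(C, D, E)` equal `(1−k, k·W, 1−k)` — so a device
pulsed per spike *is* the trace. For the default device and `kz = 1/11`
over a 0.5 ms drive phase:

```r
library(membcpnn)
cal <- calibrate_stage(1/11)
sprintf("v_exc = %.1f mV, v_inh = %.1f mV", cal$v_exc*1000, cal$v_inh*1000)
#> "v_exc = 193.2 mV, v_inh = -149.9 mV"
```

On top of the device model sit an exact reference implementation of the
rule (`run_reference()`), a behavioral emulation of the five-memristor
sample-and-hold synapse (`run_emulation()`, scalable to hypercolumn
arrays with `run_hcu()`), synthetic spike scenarios (`gen_dense()`,
`gen_overlap()`, `gen_separated()`) and a comparison harness
(`compare_traces()`).

## Worked example

Five seconds of 20 Hz dense Poisson spiking through the emulated
synapse versus the reference rule:

```r
library(membcpnn)
sc  <- gen_dense(duration = 5, rate = 20, seed = 101)
ref <- run_reference(sc$s_i, sc$s_j)
emu <- run_emulation(sc$s_i, sc$s_j)
as.data.frame(compare_traces(ref, emu))
#>    trace mean_error max_error     rmse pearson_r
#> 1    z_i   7.04e-18  5.55e-17 1.10e-17         1
#> 2    z_j   6.99e-18  8.33e-17 1.18e-17         1
#> 3    p_i   3.22e-17  8.33e-17 3.76e-17         1
#> 4    p_j   2.62e-17  9.02e-17 3.23e-17         1
#> 5   p_ij   3.49e-18  1.19e-17 4.32e-18         1
#> 6   w_ij   8.78e-15  3.55e-14 1.09e-14         1
#> 7 beta_j   9.81e-16  3.11e-15 1.17e-15         1
```

Each row scores one trace of the cascade: the Z rows are identical to
machine precision (the calibrated pulses reproduce the Z recursion
exactly), and the P, weight and bias rows differ only by accumulated
floating-point rounding of the per-step solved drive voltages —
correlation 1 throughout. A coincident-burst scenario
(`gen_overlap()`) shows the weight potentiating during activity and
relaxing to 0 in silence; disjoint bursts (`gen_separated()`) show the
depression-and-recovery mirror image.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/membcpnn simulate --scenario dense --seed 3 --out-prefix run
Rscript inst/cli/membcpnn calibrate
Rscript inst/cli/membcpnn compare run_ref.csv run_emu.csv
```

See `vignettes/memristor-bcpnn.Rmd` for the model, the calibration
algebra, the two P-stage drive modes and the package's numerical
conventions.

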