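# Shared fixtures: everything is generated in code at test time.

dp <- device_params()       # reference device, affine window
bp <- bcpnn_params()        # kz = 1/11, kp = 1/500, eps = 0.01, dt = 1 ms

# a reproducible random binary train
rand_spikes <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  as.numeric(stats::runif(n) < p)
}

# independent closed-form oracle for one Euler drive pulse in the
# affine window regime (direct arithmetic, no package code)
euler_pulse_oracle <- function(x, v, duration, params = dp) {
  if (v >= params$v_off) {
    rate <- duration * params$k_off * (v / params$v_off - 1)^params$alpha_off
    x * (1 - rate / params$w_max) + rate / params$w_max
  } else if (v <= params$v_on) {
    x * (1 + duration * params$k_on / params$w_max *
           (v / params$v_on - 1)^params$alpha_on)
  } else x
}
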