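#' Pulse schedule of the two-phase timestep
#'
#' Each simulation timestep `dt` is split into a sampling phase (device
#' resistances are read into held voltages) and a drive phase of length
#' `drive_fraction * dt` during which update voltages are applied. The
#' drive phase may be subdivided into `sub_pulses` equal sub-pulses (one
#' for the Z stages; two for the P stages in the exact drive mode, which
#' needs a decay pulse followed by a potentiation pulse).
#'
#' @param dt Timestep (s), default 1 ms.
#' @param drive_fraction Fraction of `dt` spent driving, in `(0, 1]`
#'   (default 0.5 — the split under which the reference device
#'   parameters reproduce the design drive voltages of 193.2 mV and
#'   -149.9 mV for `kz = 1/11`).
#' @param sub_pulses Sub-pulses per drive phase, `>= 1`.
#' @return An object of class `pulse_schedule` with the per-sub-pulse
#'   duration precomputed as `sub_duration`.
#' @export
pulse_schedule <- function(dt = 1e-3, drive_fraction = 0.5, sub_pulses = 1L) {
  stopifnot(dt > 0, drive_fraction > 0, drive_fraction <= 1, sub_pulses >= 1)
  structure(list(dt = dt, drive_fraction = drive_fraction,
                 sub_pulses = as.integer(sub_pulses),
                 sub_duration = drive_fraction * dt / sub_pulses),
            class = "pulse_schedule")
}

#' Affine update coefficients of a single Euler drive pulse
#'
#' In the affine window regime (`window_p = 1`, `window_j = 1`) a single
#' Euler step of the VTEAM state equation under a constant voltage is an
#' affine map of the state: `w' = C w + D` for a positive (potentiating)
#' pulse and `w' = E w` for a negative (depressing) pulse, with
#' `C = 1 - t k_off / W (v/v_off - 1)^alpha_off`,
#' `D = t k_off (v/v_off - 1)^alpha_off` and
#' `E = 1 + t k_on / W (v/v_on - 1)^alpha_on`. A dead-zone voltage
#' returns the identity `(1, 0, 1)`.
#'
#' @param v Drive voltage (V).
#' @param duration Pulse duration (s).
#' @param params A [device_params()]; must have `window_p = 1` and
#'   `window_j = 1` (the mapping is not affine otherwise).
#' @return A list with elements `C`, `D` (nm) and `E`.
#' @export
update_coefficients <- function(v, duration, params = device_params()) {
  if (params$window_p != 1 || params$window_j != 1)
    stop("affine update coefficients require window_p = 1 and window_j = 1")
  stopifnot(duration >= 0)
  C <- 1; D <- 0; E <- 1
  if (v >= params$v_off) {
    rate <- duration * params$k_off * (v / params$v_off - 1)^params$alpha_off
    C <- 1 - rate / params$w_max
    D <- rate
  } else if (v <= params$v_on) {
    E <- 1 + duration * params$k_on / params$w_max *
      (v / params$v_on - 1)^params$alpha_on
  }
  list(C = C, D = D, E = E)
}

#' Solve the drive voltage realizing a trace smoothing step
#'
#' Inverts the affine update coefficients: finds the voltage whose
#' single Euler pulse of the given duration realizes the trace update
#' with smoothing constant `target_k` — i.e. `C = 1 - k`, `D = k W`
#' (excitatory) or `E = 1 - k` (inhibitory). Closed form:
#' `v = v_off (1 + (k W / (t k_off))^(1/alpha_off))` for the excitatory
#' branch and `v = v_on (1 + (k W / (t |k_on|))^(1/alpha_on))` for the
#' inhibitory branch. With the reference device, `k = 1/11` and a 0.5 ms
#' drive phase this yields the design voltages 193.2 mV and -149.9 mV.
#'
#' @param target_k Target smoothing constant in `[0, 1)`.
#' @param polarity `"excitatory"` (state grows) or `"inhibitory"`
#'   (state decays).
#' @param duration Pulse duration (s), `> 0`.
#' @param params A [device_params()].
#' @param v_max Reachability budget on `|v|` (V); a solution beyond it
#'   is an error.
#' @return Drive voltage in V (negative for the inhibitory branch).
#' @export
#' @examples
#' solve_drive_voltage(1 / 11, "excitatory", 5e-4)   # 0.19316 V
#' solve_drive_voltage(1 / 11, "inhibitory", 5e-4)   # -0.14987 V
solve_drive_voltage <- function(target_k,
                                polarity = c("excitatory", "inhibitory"),
                                duration, params = device_params(),
                                v_max = 1) {
  polarity <- match.arg(polarity)
  stopifnot(duration > 0, v_max > 0)
  if (target_k < 0 || target_k >= 1)
    stop("target_k must lie in [0, 1)")
  if (target_k == 0) {
    warning("target_k = 0: returning the threshold voltage (zero drift)")
    return(if (polarity == "excitatory") params$v_off else params$v_on)
  }
  v <- if (polarity == "excitatory") {
    params$v_off *
      (1 + (target_k * params$w_max / (duration * params$k_off))^
             (1 / params$alpha_off))
  } else {
    params$v_on *
      (1 + (target_k * params$w_max / (duration * abs(params$k_on)))^
             (1 / params$alpha_on))
  }
  if (abs(v) > v_max)
    stop("solved drive voltage |", signif(v, 6), "| V exceeds the ",
         v_max, " V budget: smoothing constant ", signif(target_k, 6),
         " is unreachable in a ", duration, " s pulse")
  v
}

#' Calibrate one trace stage
#'
#' Solves the excitatory and inhibitory drive voltages whose single
#' sub-pulse realizes the trace update with constant `target_k`, and
#' records the target coefficients `A = 1 - k`, `B = k` alongside the
#' achieved device coefficients `C`, `D`, `E`.
#'
#' @param target_k Trace smoothing constant in `(0, 1)`.
#' @param schedule A [pulse_schedule()]; the sub-pulse duration
#'   `schedule$sub_duration` is the solved pulse length.
#' @param params A [device_params()].
#' @param v_max Reachability budget on `|v|` (V).
#' @return An object of class `stage_calibration`: `v_exc`, `v_inh`,
#'   `target_k`, `duration`, target `A`, `B` and achieved `C`, `D`, `E`.
#' @export
calibrate_stage <- function(target_k, schedule = pulse_schedule(),
                            params = device_params(), v_max = 1) {
  dur <- schedule$sub_duration
  v_exc <- solve_drive_voltage(target_k, "excitatory", dur, params, v_max)
  v_inh <- solve_drive_voltage(target_k, "inhibitory", dur, params, v_max)
  co_e <- update_coefficients(v_exc, dur, params)
  co_i <- update_coefficients(v_inh, dur, params)
  structure(list(target_k = target_k, duration = dur, schedule = schedule,
                 v_exc = v_exc, v_inh = v_inh,
                 A = 1 - target_k, B = target_k,
                 C = co_e$C, D = co_e$D, E = co_i$E),
            class = "stage_calibration")
}

#' Certify Z-stage exactness on a spike train
#'
#' Drives a device from `w = 0` with the calibrated excitatory voltage
#' on each spike and the inhibitory voltage on each silence, and returns
#' the maximum absolute deviation between the device state trajectory
#' `x` and the reference Z-trace trajectory on the same train. In the
#' affine window regime the two recursions are algebraically identical,
#' so the deviation is at floating-point rounding level.
#'
#' @param spikes Binary spike vector (may be empty, returning 0).
#' @param calib A [calibrate_stage()] result.
#' @param params A [device_params()].
#' @return `max |x - Z|` over the train.
#' @export
certify_z_exactness <- function(spikes, calib, params = device_params()) {
  if (length(spikes) == 0) return(0)
  if (!all(spikes %in% c(0, 1))) stop("spike train must be binary (0/1)")
  st <- device_state(0, params)
  z <- 0
  dev <- 0
  for (s in spikes) {
    v <- if (s == 1) calib$v_exc else calib$v_inh
    st <- apply_pulse(st, v, calib$duration, params)
    z <- z_step(z, s, calib$target_k)
    dev <- max(dev, abs(st$w / params$w_max - z))
  }
  dev
}
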