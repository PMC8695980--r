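#' Behavioral readout chain of the sample-and-hold circuit
#'
#' Parameters of the analog chain that observes and combines device
#' states: a constant current source converts the memristor resistance
#' into a sampled voltage, an amplifier normalizes it to a trace
#' estimate, a Gilbert-cell multiplier forms the `Z_i * Z_j` product and
#' logarithmic blocks compute the weight and bias. All blocks are
#' behavioral and ideal by default; `amp_gain`, `mult_gain` and
#' `mult_offset` allow injecting gain/offset imperfections.
#'
#' @param i_read Read current (A). The default 50 nA keeps the largest
#'   sampled voltage `i_read * r_off = 10 mV` below the 20 mV switching
#'   threshold of the reference device, so readout is non-destructive.
#' @param amp_gain Readout amplifier normalization (1 = ideal).
#' @param mult_gain,mult_offset Multiplier gain and offset
#'   (1 and 0 = ideal four-quadrant product).
#' @return An object of class `readout_chain`.
#' @export
readout_chain <- function(i_read = 50e-9, amp_gain = 1,
                          mult_gain = 1, mult_offset = 0) {
  stopifnot(i_read > 0)
  structure(list(i_read = i_read, amp_gain = amp_gain,
                 mult_gain = mult_gain, mult_offset = mult_offset),
            class = "readout_chain")
}

#' Sample a device state through the readout chain
#'
#' The read current converts the resistance into a voltage
#' `v_s = i_read * R`; inverting the affine resistance map recovers the
#' normalized state, scaled by the amplifier gain. With ideal gains the
#' estimate equals `x` exactly, and the sub-threshold read leaves the
#' device untouched.
#'
#' @param state A [device_state()].
#' @param chain A [readout_chain()].
#' @param params A [device_params()].
#' @return The trace estimate (dimensionless).
#' @export
sample_readout <- function(state, chain, params) {
  if (chain$i_read * params$r_off >= params$v_off)
    stop("destructive readout: i_read * r_off = ",
         chain$i_read * params$r_off, " V reaches the switching threshold ",
         params$v_off, " V")
  v_s <- chain$i_read * read_resistance(state, params)
  (v_s / chain$i_read - params$r_on) / (params$r_off - params$r_on) *
    chain$amp_gain
}

#' Behavioral Gilbert-cell product of two Z estimates
#'
#' @param z_i_est,z_j_est Trace estimates in `[0, 1]`.
#' @param chain A [readout_chain()].
#' @return `mult_gain * z_i * z_j + mult_offset`.
#' @export
multiply_z <- function(z_i_est, z_j_est, chain = readout_chain()) {
  if (z_i_est < 0 || z_i_est > 1 || z_j_est < 0 || z_j_est > 1)
    stop("multiplier inputs must lie in [0, 1]")
  chain$mult_gain * z_i_est * z_j_est + chain$mult_offset
}

#' Drive a P-stage device toward a held target
#'
#' Applies the drive-phase voltage pulses that move a P-trace device
#' toward the held target (a sampled Z value or Z product) so that its
#' state follows the P-trace recursion `P' = P (1 - kp) + target * kp`.
#'
#' Two modes:
#' * `exact_dual_pulse` — a depressing sub-pulse with rate
#'   `d = kp (1 - target) / (1 - kp * target)` followed by a
#'   potentiating sub-pulse with rate `g = kp * target`, each solved by
#'   [solve_drive_voltage()]. The composite update
#'   `x (1-d)(1-g) + g = x (1-kp) + kp * target` equals the P-step
#'   identically — the unique two-pulse decomposition with this
#'   property.
#' * `single_drive` — one pulse over the whole drive phase with a
#'   voltage affine in the target,
#'   `v = v_inh + target (v_exc - v_inh)` between the two solved
#'   `kp`-voltages; a coarse approximation of a circuit in which the
#'   held voltage drives the device directly (its fidelity is measured
#'   by the comparison harness, not asserted).
#'
#' @param state A [device_state()] of the P device.
#' @param target Held drive target in `[0, 1]`.
#' @param calib The P-stage [calibrate_stage()] result.
#' @param params A [device_params()].
#' @param mode `"exact_dual_pulse"` or `"single_drive"`.
#' @return The updated `device_state`.
#' @export
drive_p_stage <- function(state, target, calib, params,
                          mode = c("exact_dual_pulse", "single_drive")) {
  mode <- match.arg(mode)
  if (target < 0 || target > 1) stop("drive target outside [0, 1]")
  kp <- calib$target_k
  if (mode == "exact_dual_pulse") {
    d <- kp * (1 - target) / (1 - kp * target)
    g <- kp * target
    if (d > 0) {
      v <- solve_drive_voltage(d, "inhibitory", calib$duration, params)
      state <- apply_pulse(state, v, calib$duration, params)
    }
    if (g > 0) {
      v <- solve_drive_voltage(g, "excitatory", calib$duration, params)
      state <- apply_pulse(state, v, calib$duration, params)
    }
    state
  } else {
    v <- calib$v_inh + target * (calib$v_exc - calib$v_inh)
    apply_pulse(state, v, calib$schedule$drive_fraction * calib$schedule$dt,
                params)
  }
}

#' Assemble a five-memristor synapse unit
#'
#' The basic synapse architecture: five devices holding the `Z_i`,
#' `Z_j`, `P_i`, `P_j` and `P_ij` traces, each behind a sample-and-hold
#' circuit, plus the multiplier and logarithmic readout blocks. Each
#' timestep runs in two phases — sample (all resistances read into held
#' estimates) then drive (Z devices pulsed by the incoming spikes, P
#' devices driven toward the held Z values).
#'
#' @param device A [device_params()].
#' @param bcpnn A [bcpnn_params()]; `kz_i`, `kz_j`, `kp`, `eps` and `dt`
#'   are used.
#' @param chain A [readout_chain()].
#' @param mode P-stage drive mode, see [drive_p_stage()].
#' @param drive_fraction Fraction of `dt` spent driving (default 0.5).
#' @param v_max Drive-voltage budget passed to the calibration (V).
#' @return An object of class `synapse_unit` holding the five device
#'   states (`w`, named vector), the held estimates, the per-stage
#'   calibrations and the configuration.
#' @export
synapse_unit <- function(device = device_params(), bcpnn = bcpnn_params(),
                         chain = readout_chain(),
                         mode = c("exact_dual_pulse", "single_drive"),
                         drive_fraction = 0.5, v_max = 1) {
  mode <- match.arg(mode)
  sched_z <- pulse_schedule(bcpnn$dt, drive_fraction, 1L)
  sched_p <- pulse_schedule(bcpnn$dt, drive_fraction,
                            if (mode == "exact_dual_pulse") 2L else 1L)
  unit <- structure(list(
    w = setNames(rep(device$w_init, 5),
                 c("z_i", "z_j", "p_i", "p_j", "p_ij")),
    held = setNames(numeric(5), c("z_i", "z_j", "p_i", "p_j", "p_ij")),
    calib_zi = calibrate_stage(bcpnn$kz_i, sched_z, device, v_max),
    calib_zj = calibrate_stage(bcpnn$kz_j, sched_z, device, v_max),
    calib_p = calibrate_stage(bcpnn$kp, sched_p, device, v_max),
    device = device, bcpnn = bcpnn, chain = chain, mode = mode),
    class = "synapse_unit")
  # initial held values = first sampling of the pristine devices
  unit$held[] <- vapply(unit$w, function(w)
    sample_readout(device_state(w, device), chain, device), numeric(1))
  unit
}

#' Advance the synapse unit by one timestep
#'
#' Phase 1 (sample): all five device resistances are read into held
#' estimates; the multiplier forms the `Z_i * Z_j` product from the held
#' Z values. Phase 2 (drive): the Z devices receive the calibrated
#' excitatory/inhibitory voltage selected by the incoming spike, and the
#' P devices are driven toward their held targets. The returned readout
#' reports the post-drive sampled traces and the weight/bias computed by
#' the logarithmic blocks — the values the next sampling phase would
#' hold, index-aligned with the reference recursion's one-step delay.
#'
#' @param unit A [synapse_unit()].
#' @param s_i,s_j Incoming binary spikes (0/1).
#' @return A list with `unit` (updated) and `readout` (named list of
#'   `z_i`, `z_j`, `p_i`, `p_j`, `p_ij`, `w_ij`, `beta_j`).
#' @export
emulate_step <- function(unit, s_i, s_j) {
  if (!s_i %in% c(0, 1) || !s_j %in% c(0, 1))
    stop("spikes must be binary (0/1)")
  dv <- unit$device; ch <- unit$chain
  # phase 1: sample all five devices into the hold capacitors
  held <- vapply(unit$w, function(w)
    sample_readout(device_state(w, dv), ch, dv), numeric(1))
  unit$held <- held
  z_prod <- multiply_z(held[["z_i"]], held[["z_j"]], ch)
  # phase 2: drive
  cz <- unit$calib_zi
  v <- if (s_i == 1) cz$v_exc else cz$v_inh
  unit$w[["z_i"]] <- apply_pulse(device_state(unit$w[["z_i"]], dv), v,
                                 cz$duration, dv)$w
  cz <- unit$calib_zj
  v <- if (s_j == 1) cz$v_exc else cz$v_inh
  unit$w[["z_j"]] <- apply_pulse(device_state(unit$w[["z_j"]], dv), v,
                                 cz$duration, dv)$w
  for (nm in c("p_i", "p_j", "p_ij")) {
    tgt <- switch(nm, p_i = held[["z_i"]], p_j = held[["z_j"]],
                  p_ij = z_prod)
    unit$w[[nm]] <- drive_p_stage(device_state(unit$w[[nm]], dv), tgt,
                                  unit$calib_p, dv, unit$mode)$w
  }
  # post-drive observation (= what the next sampling phase will hold)
  est <- vapply(unit$w, function(w)
    sample_readout(device_state(w, dv), ch, dv), numeric(1))
  wb <- weight_bias(est[["p_i"]], est[["p_j"]], est[["p_ij"]],
                    unit$bcpnn$eps)
  list(unit = unit,
       readout = list(z_i = est[["z_i"]], z_j = est[["z_j"]],
                      p_i = est[["p_i"]], p_j = est[["p_j"]],
                      p_ij = est[["p_ij"]],
                      w_ij = wb$w_ij, beta_j = wb$beta_j))
}

#' Run the memristor synapse emulation over a spike train
#'
#' Iterates [emulate_step()] over a pair of binary spike trains and
#' returns the emulated trace trajectory in the same `trace_series`
#' schema as [run_reference()], so the two can be compared directly
#' with [compare_traces()].
#'
#' @inheritParams run_reference
#' @inheritParams synapse_unit
#' @return A `trace_series` data.frame (see [run_reference()]).
#' @export
run_emulation <- function(s_i, s_j, device = device_params(),
                          bcpnn = bcpnn_params(), chain = readout_chain(),
                          mode = c("exact_dual_pulse", "single_drive"),
                          drive_fraction = 0.5, v_max = 1) {
  mode <- match.arg(mode)
  check_spikes(s_i, s_j)
  unit <- synapse_unit(device, bcpnn, chain, mode, drive_fraction, v_max)
  n <- length(s_i)
  cols <- trace_columns()
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (t in seq_len(n)) {
    res <- emulate_step(unit, s_i[t], s_j[t])
    unit <- res$unit
    out[t, ] <- unlist(res$readout)[cols]
  }
  df <- data.frame(step = seq_len(n), time = seq_len(n) * bcpnn$dt,
                   s_i = s_i, s_j = s_j, out)
  trace_series(df, dt = bcpnn$dt, variant = paste0("emulated_", mode))
}
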