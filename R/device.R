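#' VTEAM memristor device parameters
#'
#' Constructs the parameter set of a voltage-controlled threshold-type
#' (VTEAM) memristor. The device is inert inside the voltage dead zone
#' `(v_on, v_off)` and its internal state `w` (doped-region width, nm)
#' drifts with a polynomial rate outside the thresholds, modulated by a
#' nonlinear dopant-drift window function (see [memristor_window()]).
#' Defaults are the reference device used throughout the package:
#' a 2 kOhm / 200 kOhm bipolar device with 20 mV thresholds, unit window
#' (`window_j = 1`, `window_p = 1`) and unit drift exponents.
#'
#' @param v_on Negative switching threshold (V), `v_on < 0`.
#' @param v_off Positive switching threshold (V), `v_off > 0`.
#' @param r_on Resistance at `w = 0` (Ohm).
#' @param r_off Resistance at `w = w_max` (Ohm); must exceed `r_on`.
#' @param k_on Drift-rate constant for the negative branch (nm/s), `< 0`.
#' @param k_off Drift-rate constant for the positive branch (nm/s), `> 0`.
#' @param alpha_on,alpha_off Dimensionless drift exponents.
#' @param w_max Maximum internal state `W` (nm).
#' @param w_init Initial internal state (nm), in `[0, w_max]`.
#' @param window_j Window magnitude `j > 0`.
#' @param window_p Window exponent `p >= 0`.
#' @return An object of class `device_params`.
#' @seealso [device_state()], [drift_rate()], [apply_pulse()]
#' @export
#' @examples
#' dp <- device_params()
#' read_resistance(device_state(0, dp), dp)  # 2 kOhm at w = 0
device_params <- function(v_on = -0.02, v_off = 0.02,
                          r_on = 2e3, r_off = 200e3,
                          k_on = -28, k_off = 21,
                          alpha_on = 1, alpha_off = 1,
                          w_max = 1, w_init = 0,
                          window_j = 1, window_p = 1) {
  stopifnot(v_on < 0, v_off > 0, r_on > 0, r_off > r_on,
            k_on < 0, k_off > 0, w_max > 0,
            w_init >= 0, w_init <= w_max,
            window_j > 0, window_p >= 0,
            alpha_on > 0, alpha_off > 0)
  structure(list(v_on = v_on, v_off = v_off, r_on = r_on, r_off = r_off,
                 k_on = k_on, k_off = k_off,
                 alpha_on = alpha_on, alpha_off = alpha_off,
                 w_max = w_max, w_init = w_init,
                 window_j = window_j, window_p = window_p),
            class = "device_params")
}

#' Memristor internal state
#'
#' @param w Internal state (doped-region width, nm) in `[0, w_max]`.
#' @param params A [device_params()] object.
#' @return An object of class `device_state` with element `w`.
#' @export
device_state <- function(w = NULL, params = device_params()) {
  if (is.null(w)) w <- params$w_init
  if (w < 0 || w > params$w_max)
    stop("device state w = ", w, " outside [0, ", params$w_max, "]")
  structure(list(w = w), class = "device_state")
}

#' Normalized device state x = w / W
#'
#' @inheritParams device_state
#' @param state A [device_state()] object.
#' @return Dimensionless state in `[0, 1]`.
#' @export
state_fraction <- function(state, params) state$w / params$w_max

#' Nonlinear dopant-drift window function
#'
#' Multiplicative factor modeling the slowdown of ionic drift near the
#' state boundaries: `j * (1 - x)^p` when the current is positive (state
#' moving toward 1) and `j * x^p` when negative. The window vanishes at
#' the boundary the state is moving toward, which both emulates the
#' physics and guarantees `x` stays in `[0, 1]` under Euler integration.
#'
#' @param x Normalized state in `[0, 1]` (vectorized).
#' @param current_sign `+1` for positive current, `-1` for negative.
#' @param j Window magnitude.
#' @param p Window exponent.
#' @return Window value in `[0, j]`.
#' @export
#' @examples
#' memristor_window(0.5, +1)  # 0.5
#' memristor_window(1,   +1)  # 0: cannot exceed the upper boundary
memristor_window <- function(x, current_sign, j = 1, p = 1) {
  if (any(x < 0 | x > 1)) stop("window argument x outside [0, 1]")
  if (!all(current_sign %in% c(-1, 1))) stop("current_sign must be +1 or -1")
  ifelse(current_sign > 0, j * (1 - x)^p, j * x^p)
}

#' Instantaneous state drift rate under an applied voltage
#'
#' Evaluates the VTEAM state equation: zero inside the dead zone
#' `(v_on, v_off)`, `k_off * (v/v_off - 1)^alpha_off * f(x)` at or above
#' the positive threshold and `k_on * (v/v_on - 1)^alpha_on * f(x)` at or
#' below the negative threshold, with the window `f` evaluated for the
#' matching current sign (voltage and current share sign through the
#' positive resistance).
#'
#' @param v Applied voltage (V).
#' @param state A [device_state()].
#' @param params A [device_params()].
#' @return Drift rate `dw/dt` in nm/s.
#' @export
drift_rate <- function(v, state, params) {
  x <- state$w / params$w_max
  if (v >= params$v_off) {
    params$k_off * (v / params$v_off - 1)^params$alpha_off *
      memristor_window(x, +1, params$window_j, params$window_p)
  } else if (v <= params$v_on) {
    params$k_on * (v / params$v_on - 1)^params$alpha_on *
      memristor_window(x, -1, params$window_j, params$window_p)
  } else {
    0
  }
}

#' Apply a constant-voltage pulse to a memristor
#'
#' Forward-Euler integration of [drift_rate()] over a pulse of the given
#' duration. With the affine window regime (`window_p = 1`,
#' `window_j = 1`) and a single substep the update is exactly the affine
#' map `w' = C w + D` (positive drive) or `w' = E w` (negative drive)
#' used by the trace calibration. Sub-machine-precision overshoot of the
#' `[0, w_max]` interval is absorbed by a clamp; anything larger aborts
#' with a request for more substeps.
#'
#' @param state A [device_state()].
#' @param v Pulse voltage (V).
#' @param duration Pulse duration (s), `>= 0`.
#' @param params A [device_params()].
#' @param substeps Number of Euler substeps, `>= 1`.
#' @return The updated `device_state`.
#' @export
apply_pulse <- function(state, v, duration, params, substeps = 1L) {
  stopifnot(duration >= 0, substeps >= 1)
  if (duration == 0) return(state)
  h <- duration / substeps
  w <- state$w
  for (k in seq_len(substeps)) {
    w <- w + h * drift_rate(v, structure(list(w = w), class = "device_state"),
                            params)
    if (w < -1e-12 || w > params$w_max + 1e-12)
      stop("Euler step overshot [0, ", params$w_max, "] (w = ", w,
           "); increase substeps")
    w <- min(max(w, 0), params$w_max)
  }
  structure(list(w = w), class = "device_state")
}

#' Read the device resistance
#'
#' Affine map of the normalized state:
#' `R = r_on + (r_off - r_on) * x`. The inverse map
#' `x = (R - r_on) / (r_off - r_on)` is exact, which is what the
#' sample-and-hold readout chain exploits.
#'
#' @inheritParams drift_rate
#' @return Resistance in Ohm.
#' @export
read_resistance <- function(state, params) {
  params$r_on + (params$r_off - params$r_on) * state$w / params$w_max
}

#' Quasi-static current-voltage sweep
#'
#' Drives the device with an arbitrary voltage waveform sampled at `dt`,
#' recording voltage, current (`i = v / R`), state and resistance at each
#' sample before the state update. Useful for plotting the pinched
#' hysteresis loop that is the model's signature sanity check.
#'
#' @param waveform Numeric vector of voltages (V).
#' @param dt Sample interval (s).
#' @param params A [device_params()].
#' @param initial Initial [device_state()].
#' @return A data.frame with columns `t`, `v`, `i`, `x`, `r`.
#' @export
iv_sweep <- function(waveform, dt, params = device_params(),
                     initial = device_state(params = params)) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)), dt > 0)
  n <- length(waveform)
  out <- data.frame(t = (seq_len(n) - 1) * dt, v = waveform,
                    i = NA_real_, x = NA_real_, r = NA_real_)
  st <- initial
  for (k in seq_len(n)) {
    r <- read_resistance(st, params)
    out$i[k] <- waveform[k] / r
    out$x[k] <- st$w / params$w_max
    out$r[k] <- r
    st <- apply_pulse(st, waveform[k], dt, params)
  }
  out
}
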