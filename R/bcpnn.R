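#' BCPNN learning-rule parameters
#'
#' Smoothing constants of the discrete-time BCPNN trace cascade. Each
#' trace is an exponential running average updated once per timestep
#' `dt`; a smoothing constant `k = dt / tau` corresponds to the time
#' constant `tau` of the underlying low-pass filter (for the P traces
#' the learning-rate modulation `kappa` is folded in:
#' `kp = dt / tau_p * kappa`). `eps` is the minimum-activity floor that
#' guards the logarithms in the weight and bias computation and sets the
#' silent-state fixed point.
#'
#' @param kz_i,kz_j Pre-/post-synaptic Z-trace smoothing constants in
#'   `(0, 1]` (default `1/11`, i.e. `tau_z = 11 ms` at `dt = 1 ms`).
#' @param ke E-trace smoothing constant (default `1/100`; only used by
#'   the `full_E` reference variant).
#' @param kp P-trace smoothing constant (default `1/500`).
#' @param eps Minimum-activity floor, `> 0` (default `0.01`).
#' @param dt Simulation timestep in seconds (default 1 ms).
#' @param kappa Learning-rate modulation folded into `kp` (default 1,
#'   kept for bookkeeping).
#' @return An object of class `bcpnn_params`.
#' @export
bcpnn_params <- function(kz_i = 1 / 11, kz_j = 1 / 11, ke = 1 / 100,
                         kp = 1 / 500, eps = 0.01, dt = 1e-3, kappa = 1) {
  ks <- c(kz_i = kz_i, kz_j = kz_j, ke = ke, kp = kp)
  if (any(ks <= 0 | ks > 1))
    stop("smoothing constants must lie in (0, 1]")
  stopifnot(eps > 0, dt > 0, kappa > 0)
  structure(list(kz_i = kz_i, kz_j = kz_j, ke = ke, kp = kp,
                 eps = eps, dt = dt, kappa = kappa,
                 tau_zi = dt / kz_i, tau_zj = dt / kz_j,
                 tau_e = dt / ke, tau_p = dt * kappa / kp),
            class = "bcpnn_params")
}

#' One Z-trace update
#'
#' `Z' = Z * (1 - kz) + S * kz`: a first-order low-pass filter of the
#' binary spike train.
#'
#' @param z Current trace value in `[0, 1]`.
#' @param s Spike indicator, 0 or 1.
#' @param kz Smoothing constant.
#' @return Updated trace value.
#' @export
z_step <- function(z, s, kz) z * (1 - kz) + s * kz

#' One E-trace update
#'
#' `E' = E * (1 - ke) + driver * ke`; the driver is the corresponding Z
#' trace (or the product `Z_i * Z_j` for the mutual trace).
#'
#' @param e Current trace value.
#' @param driver Driving value in `[0, 1]`.
#' @param ke Smoothing constant.
#' @return Updated trace value.
#' @export
e_step <- function(e, driver, ke) e * (1 - ke) + driver * ke

#' One P-trace update
#'
#' `P' = P * (1 - kp) + driver * kp`; the driver is the Z trace (or
#' `Z_i * Z_j`) in the simplified rule, or the E trace in the full rule.
#'
#' @param p Current trace value.
#' @param driver Driving value in `[0, 1]`.
#' @param kp Smoothing constant.
#' @return Updated trace value.
#' @export
p_step <- function(p, driver, kp) p * (1 - kp) + driver * kp

#' Synaptic weight and unit bias from P traces
#'
#' `w_ij = log(P_ij + eps^2) - log(P_i + eps) - log(P_j + eps)` and
#' `beta_j = log(P_j + eps)` (natural logarithm). The floor `eps`
#' guards the logs; note the *squared* floor on the mutual trace, which
#' makes `w_ij = 0` the exact fixed point of a fully silent network.
#'
#' @param p_i,p_j,p_ij P-trace values in `[0, 1]`.
#' @param eps Minimum-activity floor.
#' @return A list with elements `w_ij` and `beta_j` (log-units).
#' @export
#' @examples
#' weight_bias(0, 0, 0, eps = 0.01)  # w_ij = 0, beta_j = log(0.01)
weight_bias <- function(p_i, p_j, p_ij, eps) {
  stopifnot(eps > 0)
  list(w_ij = log(p_ij + eps^2) - log(p_i + eps) - log(p_j + eps),
       beta_j = log(p_j + eps))
}

#' Run the discrete-time BCPNN reference model
#'
#' Exact reference trajectory of the trace cascade for a pair of binary
#' spike trains. Each step uses the previous step's values (one-step
#' delay): element `t` of the spike vectors is the spike that drives
#' update `t`. The `simplified` variant (the default, and the one the
#' memristor emulation targets) feeds the Z traces directly into the P
#' traces; `full_E` inserts the E-trace stage between them.
#'
#' @param s_i,s_j Binary spike vectors of equal length.
#' @param params A [bcpnn_params()] object.
#' @param variant `"simplified"` (no E trace) or `"full_E"`.
#' @return A `trace_series` data.frame with columns `step`, `time`,
#'   `s_i`, `s_j`, `z_i`, `z_j`, `p_i`, `p_j`, `p_ij`, `w_ij`, `beta_j`
#'   (plus `e_i`, `e_j`, `e_ij` for the `full_E` variant), and
#'   attributes `dt` and `variant`.
#' @export
run_reference <- function(s_i, s_j, params = bcpnn_params(),
                          variant = c("simplified", "full_E")) {
  variant <- match.arg(variant)
  check_spikes(s_i, s_j)
  n <- length(s_i)
  full <- variant == "full_E"
  z_i <- z_j <- p_i <- p_j <- p_ij <- w_ij <- beta_j <- numeric(n)
  if (full) e_i <- e_j <- e_ij <- numeric(n)
  zi <- zj <- pi_ <- pj <- pij <- ei <- ej <- eij <- 0
  for (t in seq_len(n)) {
    if (full) {
      pi_n  <- p_step(pi_, ei, params$kp)
      pj_n  <- p_step(pj, ej, params$kp)
      pij_n <- p_step(pij, eij, params$kp)
      ei  <- e_step(ei, zi, params$ke)
      ej  <- e_step(ej, zj, params$ke)
      eij <- e_step(eij, zi * zj, params$ke)
    } else {
      pi_n  <- p_step(pi_, zi, params$kp)
      pj_n  <- p_step(pj, zj, params$kp)
      pij_n <- p_step(pij, zi * zj, params$kp)
    }
    zi <- z_step(zi, s_i[t], params$kz_i)
    zj <- z_step(zj, s_j[t], params$kz_j)
    pi_ <- pi_n; pj <- pj_n; pij <- pij_n
    wb <- weight_bias(pi_, pj, pij, params$eps)
    z_i[t] <- zi; z_j[t] <- zj
    p_i[t] <- pi_; p_j[t] <- pj; p_ij[t] <- pij
    w_ij[t] <- wb$w_ij; beta_j[t] <- wb$beta_j
    if (full) { e_i[t] <- ei; e_j[t] <- ej; e_ij[t] <- eij }
  }
  out <- data.frame(step = seq_len(n), time = seq_len(n) * params$dt,
                    s_i = s_i, s_j = s_j,
                    z_i = z_i, z_j = z_j,
                    p_i = p_i, p_j = p_j, p_ij = p_ij,
                    w_ij = w_ij, beta_j = beta_j)
  if (full) { out$e_i <- e_i; out$e_j <- e_j; out$e_ij <- e_ij }
  trace_series(out, dt = params$dt, variant = variant)
}

# shared spike validation: binary, equal-length, non-empty
check_spikes <- function(s_i, s_j) {
  if (length(s_i) != length(s_j))
    stop("spike trains must have equal length")
  if (length(s_i) == 0) stop("empty spike trains")
  if (!all(s_i %in% c(0, 1)) || !all(s_j %in% c(0, 1)))
    stop("spike trains must be binary (0/1)")
  invisible(TRUE)
}

# tag a data.frame as a trace series
trace_series <- function(df, dt, variant = "simplified") {
  attr(df, "dt") <- dt
  attr(df, "variant") <- variant
  class(df) <- c("trace_series", "data.frame")
  df
}

# the trace columns shared by reference and emulated series
trace_columns <- function() {
  c("z_i", "z_j", "p_i", "p_j", "p_ij", "w_ij", "beta_j")
}
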