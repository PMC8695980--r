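#' Run a memristor hypercolumn (HCU) array emulation
#'
#' Scales the basic synapse architecture to an HCU: a presynaptic vector
#' of `(Z_i, P_i)` device pairs, a postsynaptic vector of
#' `(Z_j, P_j, beta_j)` device pairs and an `n_pre x n_post` synaptic
#' matrix of `(P_ij, w_ij)` units. The per-channel Z and P devices are
#' shared across the matrix exactly as in the hardware layout, so entry
#' `(a, b)` of the weight tensor reproduces a standalone
#' [run_emulation()] on the spike pair `(pre_a, post_b)`.
#'
#' @param pre_spikes Binary matrix, `n_steps x n_pre` (a vector is
#'   treated as one column).
#' @param post_spikes Binary matrix, `n_steps x n_post`.
#' @inheritParams run_emulation
#' @return A list of class `hcu_series`: matrices `z_pre`, `p_pre`
#'   (`n_steps x n_pre`), `z_post`, `p_post`, `beta_j`
#'   (`n_steps x n_post`) and arrays `p_ij`, `w_ij`
#'   (`n_steps x n_pre x n_post`), plus `dt`.
#' @export
run_hcu <- function(pre_spikes, post_spikes, device = device_params(),
                    bcpnn = bcpnn_params(), chain = readout_chain(),
                    mode = c("exact_dual_pulse", "single_drive"),
                    drive_fraction = 0.5, v_max = 1) {
  mode <- match.arg(mode)
  pre_spikes <- as.matrix(pre_spikes)
  post_spikes <- as.matrix(post_spikes)
  if (nrow(pre_spikes) != nrow(post_spikes))
    stop("pre and post spike matrices must have the same number of steps")
  if (!all(pre_spikes %in% c(0, 1)) || !all(post_spikes %in% c(0, 1)))
    stop("spike matrices must be binary (0/1)")
  n <- nrow(pre_spikes)
  n_pre <- ncol(pre_spikes); n_post <- ncol(post_spikes)

  sched_z <- pulse_schedule(bcpnn$dt, drive_fraction, 1L)
  sched_p <- pulse_schedule(bcpnn$dt, drive_fraction,
                            if (mode == "exact_dual_pulse") 2L else 1L)
  calib_zi <- calibrate_stage(bcpnn$kz_i, sched_z, device, v_max)
  calib_zj <- calibrate_stage(bcpnn$kz_j, sched_z, device, v_max)
  calib_p <- calibrate_stage(bcpnn$kp, sched_p, device, v_max)

  w_z_pre <- rep(device$w_init, n_pre); w_p_pre <- rep(device$w_init, n_pre)
  w_z_post <- rep(device$w_init, n_post); w_p_post <- rep(device$w_init, n_post)
  w_pij <- matrix(device$w_init, n_pre, n_post)

  z_pre <- p_pre <- matrix(NA_real_, n, n_pre)
  z_post <- p_post <- beta_j <- matrix(NA_real_, n, n_post)
  p_ij <- w_ij <- array(NA_real_, c(n, n_pre, n_post))

  smp <- function(w) sample_readout(device_state(w, device), chain, device)
  drv_z <- function(w, s, calib) {
    v <- if (s == 1) calib$v_exc else calib$v_inh
    apply_pulse(device_state(w, device), v, calib$duration, device)$w
  }
  for (t in seq_len(n)) {
    # phase 1: sample every device
    h_z_pre <- vapply(w_z_pre, smp, numeric(1))
    h_z_post <- vapply(w_z_post, smp, numeric(1))
    # phase 2: drive
    for (a in seq_len(n_pre)) {
      w_z_pre[a] <- drv_z(w_z_pre[a], pre_spikes[t, a], calib_zi)
      w_p_pre[a] <- drive_p_stage(device_state(w_p_pre[a], device),
                                  h_z_pre[a], calib_p, device, mode)$w
    }
    for (b in seq_len(n_post)) {
      w_z_post[b] <- drv_z(w_z_post[b], post_spikes[t, b], calib_zj)
      w_p_post[b] <- drive_p_stage(device_state(w_p_post[b], device),
                                   h_z_post[b], calib_p, device, mode)$w
    }
    for (a in seq_len(n_pre)) for (b in seq_len(n_post)) {
      tgt <- multiply_z(h_z_pre[a], h_z_post[b], chain)
      w_pij[a, b] <- drive_p_stage(device_state(w_pij[a, b], device),
                                   tgt, calib_p, device, mode)$w
    }
    # post-drive observation
    z_pre[t, ] <- vapply(w_z_pre, smp, numeric(1))
    p_pre[t, ] <- vapply(w_p_pre, smp, numeric(1))
    z_post[t, ] <- vapply(w_z_post, smp, numeric(1))
    p_post[t, ] <- vapply(w_p_post, smp, numeric(1))
    beta_j[t, ] <- log(p_post[t, ] + bcpnn$eps)
    for (a in seq_len(n_pre)) {
      est_ij <- vapply(w_pij[a, ], smp, numeric(1))
      p_ij[t, a, ] <- est_ij
      w_ij[t, a, ] <- log(est_ij + bcpnn$eps^2) -
        log(p_pre[t, a] + bcpnn$eps) - log(p_post[t, ] + bcpnn$eps)
    }
  }
  structure(list(z_pre = z_pre, p_pre = p_pre, z_post = z_post,
                 p_post = p_post, beta_j = beta_j,
                 p_ij = p_ij, w_ij = w_ij, dt = bcpnn$dt, mode = mode),
            class = "hcu_series")
}
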