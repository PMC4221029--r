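#' The non-cerebellar PD pathway
#'
#' `u = K_p_theta * theta_e + K_d_theta * theta_dot_e + K_p_phi * phi_e +
#' K_d_phi * phi_dot_e`, clipped to \[-1, 1\]. The body-tilt pair is the
#' primary stabilizing loop; the wheel-angle pair is the secondary tracking
#' loop.
#'
#' @param theta_e,theta_dot_e body-tilt error and error velocity (rad,
#'   rad/s), reference minus measurement.
#' @param phi_e,phi_dot_e wheel-angle error and error velocity.
#' @param gains list with `kp_th`, `kd_th`, `kp_ph`, `kd_ph` (A/rad,
#'   A s/rad).
#' @return normalized command in \[-1, 1\].
#' @export
pd_control <- function(theta_e, theta_dot_e, phi_e, phi_dot_e,
                       gains = default_pd_gains()) {
  u <- gains$kp_th * theta_e + gains$kd_th * theta_dot_e +
    gains$kp_ph * phi_e + gains$kd_ph * phi_dot_e
  min(1, max(-1, u))
}

#' Combine PD and cerebellar pathways at the vestibular nucleus
#'
#' The motor command is the arithmetic subtraction of the bi-hemispheric
#' output from the PD output, clipped to \[-1, 1\].
#'
#' @param pd_out PD command in \[-1, 1\].
#' @param bicnn_out cerebellar output in \[-1, 1\].
#' @return list with `pd_out`, `bicnn_out`, `vn_out`.
#' @export
vn_combine <- function(pd_out, bicnn_out) {
  list(pd_out = pd_out, bicnn_out = bicnn_out,
       vn_out = min(1, max(-1, pd_out - bicnn_out)))
}

#' Default PD gains for the default plant
#'
#' Frozen output of [tune_pd()] on the default [plant_params()] at the
#' 0.1 Hz design task (see the methods vignette). Negative theta gains are
#' the natural orientation here: a forward lean (theta > 0) yields
#' theta_e < 0, and the corrective command must drive the wheels forward.
#'
#' @return list with `kp_th`, `kd_th`, `kp_ph`, `kd_ph`.
#' @export
default_pd_gains <- function() {
  list(kp_th = -4.836911, kd_th = -0.1282833, kp_ph = -0.1111534,
       kd_ph = -0.02223068)
}

# pd-only closed-loop run used by the tuner (engine fast path)
pd_probe <- function(gains, plant, freq, amplitude, n_steps, theta0 = 0,
                     dt = 0.01, substep = 0.001) {
  run_trial_engine("pd_only", n_steps, freq, amplitude, dt, substep,
                   onset_step = NULL, pd_gains = gains, cf = cf_params(),
                   plast = plasticity_params(), plant = plant,
                   pert = perturbation("none"), theta0 = theta0)
}

#' Ziegler-Nichols tuning of the PD pathway
#'
#' Stage 1 (ultimate gain): with only a proportional gain on the body-tilt
#' loop, the gain magnitude is raised over a geometric grid until the
#' closed loop neither falls nor decays - a sustained oscillation. The
#' smallest such magnitude is the ultimate gain K_u and the oscillation
#' period T_u is read from the zero crossings; the PD rule sets
#' `kp_th = 0.8 K_u` and `kd_th = kp_th T_u / 8`. Stage 2: wheel-loop
#' gains are picked from a small deterministic grid (both signs) as the
#' pair minimizing the wheel-angle RMSE over the 0.1 Hz design task
#' without a fall.
#'
#' @param plant [plant_params()].
#' @param design_freq design-task frequency (Hz, default 0.1).
#' @param amplitude design-task amplitude (rad).
#' @param kp_grid magnitudes scanned for the ultimate gain.
#' @param kphi_grid magnitudes scanned for the wheel-loop gain.
#' @return gains list as in [default_pd_gains()], with attributes `K_u`
#'   and `T_u`.
#' @export
tune_pd <- function(plant = plant_params(), design_freq = 0.1,
                    amplitude = pi,
                    kp_grid = exp(seq(log(0.5), log(400), length.out = 60)),
                    kphi_grid = exp(seq(log(0.01), log(2), length.out = 12))) {
  n_steps <- 1000L   # 10 s probe
  theta0 <- 0.005
  probe_theta <- function(K) {
    g <- list(kp_th = K, kd_th = 0, kp_ph = 0, kd_ph = 0)
    tr <- pd_probe(g, plant, freq = design_freq, amplitude = 0,
                   n_steps = n_steps, theta0 = theta0)
    th <- tr$df$theta
    list(fell = !is.na(tr$fall_step), theta = th)
  }
  # Raise the proportional gain through the grid; the stabilizable band of
  # an inverted pendulum under sampled P-only control is an interval, and
  # the classic "sustained oscillation at the ultimate gain" appears at its
  # upper edge: record every oscillating non-falling gain and keep the last
  # one seen before instability resumes.
  K_u <- NA_real_; T_u <- NA_real_
  for (sgn in c(-1, 1)) {
    for (K in kp_grid) {
      r <- probe_theta(sgn * K)
      if (!r$fell) {
        # period from mean zero-crossing interval over the second half; a
        # non-falling run without crossings is runaway drift, not oscillation
        th <- r$theta[(n_steps %/% 2):n_steps]
        cross <- which(diff(sign(th)) != 0)
        if (length(cross) >= 3) {
          K_u <- sgn * K
          T_u <- 2 * mean(diff(cross)) * 0.01
        }
      } else if (!is.na(K_u)) break
    }
    if (!is.na(K_u)) break
  }
  if (is.na(K_u))
    stop("no sustained oscillation found within the gain search range")
  kp_th <- 0.8 * K_u
  kd_th <- kp_th * T_u / 8
  # stage 2: wheel loop on the design task
  best <- NULL; best_rse <- Inf
  n_design <- as.integer(3 / design_freq / 0.01)
  for (sgn in c(1, -1)) for (Kp in kphi_grid) for (dr in c(0.2, 0.5)) {
    g <- list(kp_th = kp_th, kd_th = kd_th, kp_ph = sgn * Kp,
              kd_ph = sgn * Kp * dr)
    tr <- pd_probe(g, plant, freq = design_freq, amplitude = amplitude,
                   n_steps = n_design)
    if (is.na(tr$fall_step)) {
      rse <- sqrt(mean((tr$df$phi_ref - tr$df$phi)^2))
      if (rse < best_rse) { best_rse <- rse; best <- g }
    }
  }
  if (is.null(best))
    stop("no wheel-loop gains tracked the design task without falling")
  structure(best, K_u = K_u, T_u = T_u, design_rse = best_rse)
}
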