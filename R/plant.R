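#' Parameters of the simulated two-wheel balancing robot
#'
#' A planar wheeled-inverted-pendulum: a body of mass `body_mass` whose
#' center of mass sits `body_com_length` above the wheel axle, on wheels of
#' total mass `wheel_mass` and radius `wheel_radius`. The motor applies a
#' torque `motor_torque_per_unit_command * u` between body and wheels for a
#' normalized command u in \[-1, 1\]. Viscous friction acts on the
#' translation; `friction_asym` makes it slightly direction dependent
#' (positive = more friction moving forward), emulating the intrinsic
#' forward/backward asymmetry of a real robot's mechanics. The robot is
#' considered fallen (latched) once |theta| exceeds `fall_threshold`.
#'
#' @param ... overrides of any default field.
#' @return named list of plant constants.
#' @export
plant_params <- function(...) {
  p <- list(body_mass = 0.6,          # kg
            wheel_mass = 0.08,        # kg, both wheels + rotor
            wheel_radius = 0.025,     # m
            body_com_length = 0.07,   # m, axle to COM
            body_inertia = NULL,      # kg m^2 about COM; default slender-rod
            motor_torque_per_unit_command = 0.25,  # N m at u = 1
            viscous_friction = 0.35,  # N s/m on translation
            friction_asym = 0.05,     # fractional fore/aft asymmetry
            theta_damping = 0.01,     # N m s/rad on body pitch
            gravity = 9.81,
            fall_threshold = pi / 6)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  if (is.null(p$body_inertia))
    p$body_inertia <- p$body_mass * (2 * p$body_com_length)^2 / 12
  stopifnot(p$body_mass > 0, p$wheel_mass > 0, p$wheel_radius > 0,
            p$body_com_length > 0)
  p
}

#' Perturbation descriptor
#'
#' `load_*` kinds attach a point mass to the body (`load_mass`, default
#' 300 g = 50% of the robot's mass) at height `load_height` along the body
#' axis, displaced `load_offset` fore (+) or aft (-) of the axis;
#' `incline`/`decline` tilt the platform by `platform_angle` (+/-10 deg).
#'
#' @param kind one of `none`, `load_center`, `load_front`, `load_back`,
#'   `incline`, `decline`.
#' @param load_mass kg.
#' @param load_offset m, magnitude of the fore/aft displacement for the
#'   off-center loads.
#' @param load_height m along the body axis above the axle; `NULL` picks
#'   the per-kind default (0.175 for the on-top centered load, 0.16 for
#'   the off-center loads, which hang lower on the frame).
#' @param platform_angle rad, magnitude of the platform tilt.
#' @return named list with the resolved signed fields.
#' @export
perturbation <- function(kind = c("none", "load_center", "load_front",
                                  "load_back", "incline", "decline"),
                         load_mass = 0.3, load_offset = 0.02,
                         load_height = NULL, platform_angle = 10 * pi / 180) {
  kind <- match.arg(kind)
  if (is.null(load_height))
    load_height <- if (kind == "load_center") 0.175 else 0.16
  out <- list(kind = kind, load_mass = 0, load_offset = 0,
              load_height = load_height, platform_angle = 0)
  if (kind %in% c("load_center", "load_front", "load_back")) {
    out$load_mass <- load_mass
    out$load_offset <- switch(kind, load_front = load_offset,
                              load_back = -load_offset, 0)
  }
  if (kind == "incline") out$platform_angle <- platform_angle
  if (kind == "decline") out$platform_angle <- -platform_angle
  out
}

# Resolve plant + perturbation into the constants of the equations of motion:
# effective body mass m_b, COM distance L and angular offset delta, inertia
# about the axle J, slope alpha. The body + load composite is exact for a
# rigid pendulum: first moments add vectorially, second moments add scalarly.
resolve_plant <- function(params, pert = perturbation("none")) {
  mb <- params$body_mass
  l <- params$body_com_length
  mL <- pert$load_mass
  mx <- mb * l + mL * pert$load_height        # axial first moment
  my <- mL * pert$load_offset                 # fore/aft first moment
  m_eff <- mb + mL
  L <- sqrt(mx^2 + my^2) / m_eff
  delta <- atan2(my, mx)
  J <- params$body_inertia + mb * l^2 +
    mL * (pert$load_height^2 + pert$load_offset^2)
  Iw <- 0.5 * params$wheel_mass * params$wheel_radius^2
  list(m_eff = m_eff, m_tot = m_eff + params$wheel_mass,
       L = L, delta = delta, J = J,
       s_inertia = m_eff + params$wheel_mass + Iw / params$wheel_radius^2,
       alpha = pert$platform_angle,
       r = params$wheel_radius, g = params$gravity,
       k_tau = params$motor_torque_per_unit_command,
       c_s = params$viscous_friction, asym = params$friction_asym,
       c_th = params$theta_damping)
}

# accelerations (s_ddot, theta_ddot) of the resolved plant
plant_accel <- function(th, th_dot, s_dot, tau, q) {
  cs <- cos(th + q$delta + q$alpha)
  mlc <- q$m_eff * q$L * cs
  fric <- q$c_s * (1 + q$asym * sign(s_dot)) * s_dot
  b1 <- q$m_eff * q$L * sin(th + q$delta + q$alpha) * th_dot^2 +
    tau / q$r - fric - q$m_tot * q$g * sin(q$alpha)
  b2 <- q$m_eff * q$g * q$L * sin(th + q$delta) - tau - q$c_th * th_dot
  a11 <- q$s_inertia; a22 <- q$J
  det <- a11 * a22 - mlc^2
  c((a22 * b1 - mlc * b2) / det,    # s_ddot
    (a11 * b2 - mlc * b1) / det)    # theta_ddot
}

#' Advance the plant by one control period
#'
#' Integrates the coupled (theta, phi) rigid-body equations with RK4 at
#' `substep` resolution inside the `dt` control period, applying the motor
#' torque `tau = motor_torque_per_unit_command * u`. Load perturbations
#' shift the composite mass, center of mass and inertia; a platform angle
#' adds the gravity component along the slope. The fallen flag latches once
#' |theta| crosses the fall threshold, after which the state is frozen.
#'
#' @param state list/vector with `theta`, `theta_dot`, `phi`, `phi_dot`
#'   (and optionally `fallen`).
#' @param u normalized motor command in \[-1, 1\].
#' @param params [plant_params()].
#' @param pert [perturbation()].
#' @param dt control period (s), default 0.010.
#' @param substep internal RK4 step (s), default 0.001.
#' @return updated state list (theta, theta_dot, phi, phi_dot, fallen).
#' @export
plant_step <- function(state, u, params = plant_params(),
                       pert = perturbation("none"), dt = 0.010,
                       substep = 0.001) {
  q <- resolve_plant(params, pert)
  fallen <- isTRUE(state$fallen)
  if (fallen)
    return(list(theta = state$theta, theta_dot = state$theta_dot,
                phi = state$phi, phi_dot = state$phi_dot, fallen = TRUE))
  tau <- q$k_tau * min(1, max(-1, u))
  y <- c(s = state$phi * q$r, th = state$theta,
         s_dot = state$phi_dot * q$r, th_dot = state$theta_dot)
  deriv <- function(y) {
    acc <- plant_accel(y[2], y[4], y[3], tau, q)
    c(y[3], y[4], acc[1], acc[2])
  }
  n_sub <- max(1L, round(dt / substep))
  h <- dt / n_sub
  for (i in seq_len(n_sub)) {
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (any(!is.finite(y))) stop("plant integration produced non-finite state")
  fallen <- abs(y[2]) > params$fall_threshold
  list(theta = unname(y[2]), theta_dot = unname(y[4]),
       phi = unname(y[1] / q$r), phi_dot = unname(y[3] / q$r),
       fallen = fallen)
}

# total mechanical energy of the resolved plant (for conservation checks)
plant_energy <- function(state, params, pert = perturbation("none")) {
  q <- resolve_plant(params, pert)
  s <- state$phi * q$r; s_dot <- state$phi_dot * q$r
  ke <- 0.5 * q$s_inertia * s_dot^2 + 0.5 * q$J * state$theta_dot^2 +
    q$m_eff * q$L * s_dot * state$theta_dot *
      cos(state$theta + q$delta + q$alpha)
  pe <- q$m_tot * q$g * s * sin(q$alpha) +
    q$m_eff * q$g * q$L * cos(state$theta + q$delta)
  ke + pe
}

#' Reference trajectory for the tracking task
#'
#' Wheel-angle reference `amplitude * sin(2 pi freq t)` with its analytic
#' derivative; body-tilt references are identically zero (the robot must
#' stay vertical while tracking).
#'
#' @param t time (s), scalar or vector.
#' @param freq Hz (default 0.25).
#' @param amplitude rad (default pi).
#' @return list with `phi_ref`, `phi_dot_ref`, `theta_ref`,
#'   `theta_dot_ref` and the zero-based `cycle` index `floor(t * freq)`.
#' @export
reference_trajectory <- function(t, freq = 0.25, amplitude = pi) {
  stopifnot(freq > 0)
  w <- 2 * pi * freq
  list(phi_ref = amplitude * sin(w * t),
       phi_dot_ref = amplitude * w * cos(w * t),
       theta_ref = rep(0, length(t)), theta_dot_ref = rep(0, length(t)),
       cycle = floor(t * freq))
}

#' Read the robot's sensors
#'
#' Returns the true state, optionally with encoder quantization on the
#' wheel angle and additive Gaussian gyro noise on the tilt signals; both
#' default off. Noise draws use the current RNG stream, so seeding the
#' session makes the stream reproducible.
#'
#' @param state plant state list.
#' @param noise_cfg list with `encoder_quant` (rad) and `gyro_sd` (rad/s
#'   scale, applied to theta and theta_dot); `NULL` entries disable.
#' @return list with measured `theta`, `theta_dot`, `phi`, `phi_dot`.
#' @export
read_sensors <- function(state, noise_cfg = list()) {
  th <- state$theta; thd <- state$theta_dot
  ph <- state$phi; phd <- state$phi_dot
  q <- noise_cfg$encoder_quant
  if (!is.null(q) && q > 0) {
    ph <- round(ph / q) * q
    phd <- round(phd / q) * q
  }
  sd <- noise_cfg$gyro_sd
  if (!is.null(sd) && sd > 0) {
    th <- th + stats::rnorm(1, 0, sd)
    thd <- thd + stats::rnorm(1, 0, sd)
  }
  list(theta = th, theta_dot = thd, phi = ph, phi_dot = phd)
}
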