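#' Knee-extension plant parameters
#'
#' Shank-against-gravity plant: a one-pole muscle activation stage maps
#' stimulus pulse width to active quadriceps torque,
#' `dT_a/dt = (G * pw - T_a) / tau`, feeding nonlinear second-order shank
#' dynamics `J * theta'' = T_a - mgl * sin(theta) - B * theta' -
#' K * (theta - rest)` with hard stops at 0 and 90 degrees (0 deg = shank
#' hanging at rest, positive = extension).
#'
#' The defaults are this package's own desk-scale constants, not values
#' from any measured subject.  They were fixed once, analytically, so that
#' the passive joint is stiffness-dominated near extension (a linear proxy
#' for the steeply rising passive elastic moment of the knee) and the
#' closed loop settles at each supported reference angle; the methods
#' vignette derives them.
#'
#' @param J moment of inertia of the shank about the knee (kg m^2).
#' @param mgl gravitational moment coefficient m*g*l (N m); gravity torque
#'   is `mgl * sin(theta)`.
#' @param B viscous damping (N m s / rad).
#' @param K passive stiffness (N m / rad) about `rest`.
#' @param rest resting angle of the passive elastic term (rad).
#' @param G torque gain (N m per microsecond of pulse width).
#' @param tau muscle activation time constant (s).
#' @return an object of class `plant_params`.
#' @export
plant_params <- function(J = 0.9, mgl = 0.03, B = 2.4, K = 1.2,
                         rest = 0, G = 0.00396007, tau = 0.5) {
  stopifnot(J > 0, tau > 0, B >= 0, K >= 0, G >= 0, mgl >= 0)
  structure(list(J = J, mgl = mgl, B = B, K = K, rest = rest,
                 G = G, tau = tau),
            class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Knee-extension plant parameters\n")
  cat(sprintf("  J = %g kg m^2, mgl = %g N m, B = %g N m s/rad, K = %g N m/rad\n",
              x$J, x$mgl, x$B, x$K))
  cat(sprintf("  rest = %g rad, G = %g N m/us, tau = %g s\n",
              x$rest, x$G, x$tau))
  invisible(x)
}

#' Plant state
#'
#' @param theta knee angle in degrees (0 = hanging, positive = extension).
#' @param omega angular velocity in degrees per second.
#' @param torque active muscle torque T_a in N m.
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(theta = 0, omega = 0, torque = 0) {
  stopifnot(is.finite(theta), is.finite(omega), is.finite(torque))
  structure(list(theta = theta, omega = omega, torque = torque),
            class = "plant_state")
}

#' Advance the muscle activation stage by one step (exact update)
#'
#' First-order lag `dT_a/dt = (G * pw - T_a) / tau`, discretized exactly:
#' `T_a' = G*pw + (T_a - G*pw) * exp(-dt / tau)`.
#'
#' @param T_a current active torque (N m).
#' @param pulse_width_us stimulus pulse width held over the step.
#' @param params a [plant_params()].
#' @param dt step in seconds, > 0.
#' @return new active torque.
#' @export
activation_step <- function(T_a, pulse_width_us, params, dt) {
  stopifnot(dt > 0)
  target <- params$G * pulse_width_us
  target + (T_a - target) * exp(-dt / params$tau)
}

# net joint moment (N m) at angle theta (deg) and velocity omega (deg/s)
joint_accel <- function(theta, omega, T_a, p) {
  d2r <- pi / 180
  torque <- T_a - p$mgl * sin(theta * d2r) - p$B * (omega * d2r) -
    p$K * (theta * d2r - p$rest)
  (torque / p$J) / d2r  # deg/s^2
}

#' Advance the shank dynamics by one fixed step (4th-order Runge-Kutta)
#'
#' Integrates `J theta'' = T_a - mgl sin(theta) - B theta' - K (theta -
#' rest)` with the active torque held constant over the step, then applies
#' the hard stops: the angle is clamped to 0..90 degrees and the velocity
#' zeroed on contact.
#'
#' @param state a [plant_state()].
#' @param T_a active torque held over the step (N m).
#' @param params a [plant_params()].
#' @param dt step in seconds; <= 1 ms for the documented accuracy.
#' @return new [plant_state()] (torque field unchanged).
#' @export
dynamics_step <- function(state, T_a, params, dt) {
  stopifnot(dt > 0, dt <= 1e-3 + 1e-12)
  th <- state$theta; om <- state$omega
  if (!is.finite(th) || !is.finite(om)) stop("non-finite plant state")
  k1t <- om;                    k1o <- joint_accel(th, om, T_a, params)
  k2t <- om + dt / 2 * k1o;     k2o <- joint_accel(th + dt / 2 * k1t, k2t, T_a, params)
  k3t <- om + dt / 2 * k2o;     k3o <- joint_accel(th + dt / 2 * k2t, k3t, T_a, params)
  k4t <- om + dt * k3o;         k4o <- joint_accel(th + dt * k3t, k4t, T_a, params)
  th2 <- th + dt / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
  om2 <- om + dt / 6 * (k1o + 2 * k2o + 2 * k3o + k4o)
  if (th2 <= 0)  { th2 <- 0;  if (om2 < 0) om2 <- 0 }
  if (th2 >= 90) { th2 <- 90; if (om2 > 0) om2 <- 0 }
  plant_state(th2, om2, state$torque)
}

#' Simulate the plant under a piecewise-constant pulse-width command
#'
#' Zero-order hold: each commanded pulse width is held for
#' `sample_period_s` while the plant integrates at the inner step `dt`.
#' The activation stage advances with its exact exponential update; the
#' torque fed to the shank dynamics over each inner step is the exact
#' mid-step activation value, which keeps the coupled integration
#' second-order accurate.
#'
#' @param pulse_widths_us vector of pulse-width commands (microseconds),
#'   one per controller sample.
#' @param params a [plant_params()].
#' @param state initial [plant_state()].
#' @param sample_period_s hold time per command (default 0.1 s).
#' @param dt inner integration step in seconds (default 1e-3).
#' @return data.frame with columns `t`, `theta`, `omega`, `torque`,
#'   `pulse`, sampled at every inner step (first row is the initial state).
#' @export
plant_simulate <- function(pulse_widths_us, params = plant_params(),
                           state = plant_state(), sample_period_s = 0.1,
                           dt = 1e-3) {
  n_inner <- round(sample_period_s / dt)
  stopifnot(abs(n_inner * dt - sample_period_s) < 1e-9, n_inner >= 1)
  n <- length(pulse_widths_us) * n_inner
  t <- numeric(n + 1); th <- numeric(n + 1); om <- numeric(n + 1)
  tq <- numeric(n + 1); pw <- numeric(n + 1)
  th[1] <- state$theta; om[1] <- state$omega; tq[1] <- state$torque
  pw[1] <- pulse_widths_us[1]
  k <- 1
  for (j in seq_along(pulse_widths_us)) {
    cmd <- pulse_widths_us[j]
    for (i in seq_len(n_inner)) {
      T_mid <- activation_step(state$torque, cmd, params, dt / 2)
      T_end <- activation_step(state$torque, cmd, params, dt)
      state <- dynamics_step(state, T_mid, params, dt)
      state$torque <- T_end
      k <- k + 1
      t[k] <- t[k - 1] + dt
      th[k] <- state$theta; om[k] <- state$omega; tq[k] <- state$torque
      pw[k] <- cmd
    }
  }
  data.frame(t = t, theta = th, omega = om, torque = tq, pulse = pw)
}
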