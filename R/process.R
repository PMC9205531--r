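#' Physical parameters of the simulated arm
#'
#' Bundles the constants of the generative process: the real forearm and its
#' damped dynamics, plus the standard deviations of the sensory noise added to
#' each observation channel. Defaults are average adult forearm values with
#' plausible sensory accuracies (proprioceptive noise of 0.1 rad, about 5
#' degrees; visual noise of 1 cm on the hand centre).
#'
#' @param L_arm Forearm length in meters. Must be positive.
#' @param m_arm Forearm mass in kg. Must be positive.
#' @param phi Viscosity (damping) constant of the arm dynamics.
#' @param beta Exponent of the power-law dependence of damping on velocity,
#'   in (0, 1]. The default 0.5 gives a crisp, sublinear stop instead of the
#'   long exponential tail of linear (critical) damping.
#' @param sigma_p Standard deviation of the proprioceptive noise (rad).
#' @param sigma_v Standard deviation of the visual noise (m), isotropic: the
#'   same value is applied independently to both Cartesian coordinates.
#' @param F_E External force term. Structurally present in the dynamics but
#'   fixed at 0 in all simulations.
#'
#' @return An object of class `process_params` (a named list).
#' @seealso [step_arm()], [sample_sensory()]
#' @export
#' @examples
#' process_params()
process_params <- function(L_arm = 0.45, m_arm = 1.5, phi = 4, beta = 0.5,
                           sigma_p = 0.1, sigma_v = 0.01, F_E = 0) {
  stopifnot(
    "L_arm must be a positive finite number" = is_scalar_finite(L_arm) && L_arm > 0,
    "m_arm must be a positive finite number" = is_scalar_finite(m_arm) && m_arm > 0,
    "phi must be finite and >= 0" = is_scalar_finite(phi) && phi >= 0,
    "beta must be in (0, 1]" = is_scalar_finite(beta) && beta > 0 && beta <= 1,
    "sigma_p must be finite and >= 0" = is_scalar_finite(sigma_p) && sigma_p >= 0,
    "sigma_v must be finite and >= 0" = is_scalar_finite(sigma_v) && sigma_v >= 0,
    "F_E must be finite" = is_scalar_finite(F_E)
  )
  structure(
    list(L_arm = L_arm, m_arm = m_arm, phi = phi, beta = beta,
         sigma_p = sigma_p, sigma_v = sigma_v, F_E = F_E),
    class = "process_params"
  )
}

#' Visual source regime for the hand image
#'
#' Selects where the visual input comes from. In `"real_hand"` the agent sees
#' its own hand. In `"static_fake"` the view of the real hand is replaced by a
#' fake (rubber) hand held at a fixed joint angle. In `"gained_virtual"` the
#' agent sees a virtual arm whose angular velocity is the real arm's velocity
#' multiplied by `velocity_gain`, so a gain different from 1 makes the two arms
#' drift apart as soon as the real arm moves.
#'
#' @param mode One of `"real_hand"`, `"static_fake"`, `"gained_virtual"`.
#' @param fake_theta Fixed fake-hand joint angle (rad). Required iff
#'   `mode = "static_fake"`.
#' @param velocity_gain Dimensionless velocity multiplier of the virtual arm.
#'   Required iff `mode = "gained_virtual"`; must be positive.
#'
#' @return An object of class `visual_source`.
#' @export
#' @examples
#' visual_source("static_fake", fake_theta = pi / 3)
#' visual_source("gained_virtual", velocity_gain = 1.3)
visual_source <- function(mode = c("real_hand", "static_fake", "gained_virtual"),
                          fake_theta = NULL, velocity_gain = NULL) {
  mode <- match.arg(mode)
  if (mode == "static_fake") {
    if (is.null(fake_theta) || !is_scalar_finite(fake_theta))
      stop("static_fake mode requires a finite fake_theta", call. = FALSE)
  } else if (!is.null(fake_theta)) {
    stop("fake_theta is only meaningful in static_fake mode", call. = FALSE)
  }
  if (mode == "gained_virtual") {
    if (is.null(velocity_gain) || !is_scalar_finite(velocity_gain) || velocity_gain <= 0)
      stop("gained_virtual mode requires a positive, finite velocity_gain",
           call. = FALSE)
  } else if (!is.null(velocity_gain)) {
    stop("velocity_gain is only meaningful in gained_virtual mode", call. = FALSE)
  }
  structure(list(mode = mode, fake_theta = fake_theta,
                 velocity_gain = velocity_gain),
            class = "visual_source")
}

#' State of the real arm
#'
#' The arm is described in generalized coordinates at first order: joint angle
#' and joint angular velocity. Under the gained-virtual visual regime the state
#' also carries the virtual arm's joint angle.
#'
#' @param theta Elbow joint angle (rad). 0 means the forearm is parallel to the
#'   midsagittal plane; positive angles rotate the hand toward +x.
#' @param theta_prime Joint angular velocity (rad/s).
#' @param theta_vr Virtual-arm joint angle (rad), or `NULL` when no virtual arm
#'   is displayed.
#'
#' @return An object of class `system_state`.
#' @export
system_state <- function(theta = 0, theta_prime = 0, theta_vr = NULL) {
  stopifnot(
    "theta must be finite" = is_scalar_finite(theta),
    "theta_prime must be finite" = is_scalar_finite(theta_prime),
    "theta_vr must be NULL or finite" = is.null(theta_vr) || is_scalar_finite(theta_vr)
  )
  structure(list(theta = theta, theta_prime = theta_prime, theta_vr = theta_vr),
            class = "system_state")
}

#' Forward kinematics: joint angle to Cartesian hand position
#'
#' Maps the elbow joint angle to the position of the palm centre in the 2D
#' Cartesian frame of the workspace: `(x, y) = (L sin(theta), L cos(theta))`.
#' At `theta = 0` the hand lies on the +y axis (forearm parallel to the
#' midsagittal plane); positive angles rotate it toward +x. The map is smooth
#' and injective on (-pi/2, pi/2).
#'
#' @param theta Joint angle(s) in rad.
#' @param L Forearm length in meters.
#'
#' @return For scalar `theta`, a named numeric vector `c(x, y)`; for a vector
#'   of angles, a two-column matrix with one row per angle.
#' @export
#' @examples
#' forward_map(0, 0.45)      # c(x = 0, y = 0.45)
#' forward_map(pi / 2, 0.45) # c(x = 0.45, y = 0)
forward_map <- function(theta, L = 0.45) {
  if (!all(is.finite(theta))) stop("theta must be finite", call. = FALSE)
  stopifnot("L must be positive" = is_scalar_finite(L) && L > 0)
  out <- cbind(x = L * sin(theta), y = L * cos(theta))
  if (length(theta) == 1L) out[1L, ] else out
}

#' Jacobian of the forward kinematics
#'
#' Derivative of [forward_map()] with respect to the joint angle:
#' `(L cos(theta), -L sin(theta))`. Used to propagate visual prediction errors
#' back to the joint angle in the free-energy gradients.
#'
#' @inheritParams forward_map
#' @return A named numeric vector `c(x, y)` (scalar `theta`) or a two-column
#'   matrix.
#' @export
forward_jacobian <- function(theta, L = 0.45) {
  if (!all(is.finite(theta))) stop("theta must be finite", call. = FALSE)
  stopifnot("L must be positive" = is_scalar_finite(L) && L > 0)
  out <- cbind(x = L * cos(theta), y = -L * sin(theta))
  if (length(theta) == 1L) out[1L, ] else out
}

#' Advance the arm one Euler step
#'
#' Integrates the damped arm dynamics for one explicit Euler step of length
#' `dt`:
#' \deqn{\dot\theta = \theta', \qquad
#'       \dot\theta' = A + (F_E - \phi\,\mathrm{sign}(\theta')|\theta'|^\beta)/m}
#' where `A` is the agent's action (an angular acceleration). The damping law
#' is written odd-symmetric in the velocity so it always opposes motion. In
#' gained-virtual mode the virtual angle advances as
#' `theta_vr + dt * velocity_gain * theta_prime`.
#'
#' @param state A [system_state()].
#' @param A Action (rad/s^2).
#' @param params A [process_params()].
#' @param source A [visual_source()].
#' @param dt Step length (s), positive.
#'
#' @return The updated `system_state`.
#' @export
step_arm <- function(state, A, params, source, dt) {
  stopifnot(
    inherits(state, "system_state"), inherits(params, "process_params"),
    inherits(source, "visual_source"),
    "A must be finite" = is_scalar_finite(A),
    "dt must be positive" = is_scalar_finite(dt) && dt > 0
  )
  st <- .step_arm(state$theta, state$theta_prime, state$theta_vr, A,
                  params, source, dt)
  system_state(theta = st[[1L]], theta_prime = st[[2L]], theta_vr = st[[3L]])
}

# scalar kernel shared with the simulation loop (no class overhead)
.step_arm <- function(theta, theta_prime, theta_vr, A, params, source, dt) {
  damping <- params$phi * sign(theta_prime) * abs(theta_prime)^params$beta
  theta_new <- theta + dt * theta_prime
  theta_prime_new <- theta_prime + dt * (A + (params$F_E - damping) / params$m_arm)
  if (identical(source$mode, "gained_virtual")) {
    theta_vr <- theta_vr + dt * source$velocity_gain * theta_prime
  }
  list(theta_new, theta_prime_new, theta_vr)
}

#' Draw one noisy sensory sample
#'
#' Generates the observation pair available to the agent: the proprioceptive
#' joint angle `s_p = theta + N(0, sigma_p^2)` and the visual hand position
#' `s_v = forward_map(theta_src) + N(0, sigma_v^2 I)`, where `theta_src` is
#' the real angle, the fake-hand angle, or the virtual-arm angle depending on
#' the visual source regime. Noise draws are i.i.d. per step and per channel,
#' taken from R's current RNG stream; seed the stream once per run for
#' reproducibility.
#'
#' @inheritParams step_arm
#' @return An object of class `sensory_sample`: a list with `s_p` (rad) and
#'   `s_v` (named numeric `c(x, y)`, meters).
#' @export
sample_sensory <- function(state, params, source) {
  stopifnot(inherits(state, "system_state"), inherits(params, "process_params"),
            inherits(source, "visual_source"))
  s <- .sample_sensory(state$theta, state$theta_vr, params, source)
  structure(list(s_p = s[[1L]], s_v = c(x = s[[2L]], y = s[[3L]])),
            class = "sensory_sample")
}

.visual_theta <- function(theta, theta_vr, source) {
  switch(source$mode,
         real_hand = theta,
         static_fake = source$fake_theta,
         gained_virtual = theta_vr)
}

.sample_sensory <- function(theta, theta_vr, params, source) {
  th_src <- .visual_theta(theta, theta_vr, source)
  s_p <- theta + stats::rnorm(1L, 0, params$sigma_p)
  s_v <- c(params$L_arm * sin(th_src), params$L_arm * cos(th_src)) +
    stats::rnorm(2L, 0, params$sigma_v)
  list(s_p, s_v[1L], s_v[2L])
}

is_scalar_finite <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
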