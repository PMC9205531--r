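#' Parameters of the agent's generative model
#'
#' The agent's internal description of the arm mirrors the generative process
#' (an unbiased body representation: same length and mass), but its dynamics
#' differ structurally: the internal model is a damped oscillator whose
#' equilibrium is a desired joint angle acting as a point attractor with
#' elastic constant `K_tilde`. The attractor has no counterpart in the real
#' arm; it is what lets the agent pursue goals instead of passively following
#' the environment.
#'
#' @param L_tilde Internal forearm length (m).
#' @param m_tilde Internal forearm mass (kg).
#' @param phi_tilde Internal damping constant.
#' @param K_tilde Elastic constant of the attractor (attraction strength).
#'   With the defaults, `phi_tilde^2 = 16 > 4 * K_tilde * m_tilde = 7.8`, so
#'   the internal dynamics is overdamped and does not oscillate around the
#'   goal.
#' @param sigma_sp Expected proprioceptive noise (rad) used to precision-weight
#'   the proprioceptive prediction error.
#' @param sigma_sv Expected visual noise (m), shared by both Cartesian
#'   coordinates.
#' @param sigma_mu1 Model uncertainty on the first-order internal dynamics
#'   (the velocity order). Its error is zero by construction, so this value
#'   never influences the simulation; it is kept for completeness.
#' @param sigma_mu2 Model uncertainty on the second-order internal dynamics
#'   (the acceleration order).
#'
#' @return An object of class `model_params`.
#' @export
model_params <- function(L_tilde = 0.45, m_tilde = 1.5, phi_tilde = 4,
                         K_tilde = 1.3, sigma_sp = 0.1, sigma_sv = 0.01,
                         sigma_mu1 = 0.01, sigma_mu2 = 0.1) {
  vals <- list(L_tilde = L_tilde, m_tilde = m_tilde, phi_tilde = phi_tilde,
               K_tilde = K_tilde, sigma_sp = sigma_sp, sigma_sv = sigma_sv,
               sigma_mu1 = sigma_mu1, sigma_mu2 = sigma_mu2)
  for (nm in names(vals)) {
    if (!is_scalar_finite(vals[[nm]]) || vals[[nm]] <= 0)
      stop(nm, " must be a strictly positive finite number", call. = FALSE)
  }
  structure(vals, class = "model_params")
}

#' The agent's belief state
#'
#' The internal state vector in generalized coordinates at second order:
#' inferred joint angle, velocity and acceleration, plus the desired joint
#' angle `mu_theta_T` that the internal dynamics treats as an attractor. The
#' second order is tracked because the internal dynamics predicts changes in
#' velocity, so an acceleration estimate is needed to form that prediction
#' error.
#'
#' While `resting` is `TRUE` the agent does not intend to move: the attractor
#' is re-assigned to the current angle estimate at every step of the loop, so
#' the internal dynamics prescribes no movement and the elastic term
#' contributes exactly zero model error. [set_target()] leaves the resting
#' condition.
#'
#' @param mu_theta Inferred joint angle (rad).
#' @param mu_theta_prime Inferred angular velocity (rad/s).
#' @param mu_theta_dprime Inferred angular acceleration (rad/s^2).
#' @param mu_theta_T Desired (attractor) joint angle (rad).
#' @param resting Logical; if `TRUE` the attractor tracks `mu_theta`.
#'
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(mu_theta = 0, mu_theta_prime = 0,
                         mu_theta_dprime = 0, mu_theta_T = mu_theta,
                         resting = TRUE) {
  stopifnot(
    is_scalar_finite(mu_theta), is_scalar_finite(mu_theta_prime),
    is_scalar_finite(mu_theta_dprime), is_scalar_finite(mu_theta_T),
    is.logical(resting), length(resting) == 1L, !is.na(resting)
  )
  structure(list(mu_theta = mu_theta, mu_theta_prime = mu_theta_prime,
                 mu_theta_dprime = mu_theta_dprime, mu_theta_T = mu_theta_T,
                 resting = resting),
            class = "belief_state")
}

#' Expected sensory input under the current belief
#'
#' The agent's prediction of what it should sense given its inferred state:
#' proprioception is predicted by the identity map (`mu_sp = mu_theta`) and
#' vision by the internal forward kinematics
#' (`mu_sv = forward_map(mu_theta, L_tilde)`). With an unbiased internal
#' length this equals the noise-free observation of the real hand at the same
#' angle.
#'
#' @param belief A [belief_state()].
#' @param model A [model_params()].
#' @return A list with `mu_sp` (rad) and `mu_sv` (named `c(x, y)`, meters).
#' @export
expected_sensory <- function(belief, model) {
  stopifnot(inherits(belief, "belief_state"), inherits(model, "model_params"))
  list(mu_sp = belief$mu_theta,
       mu_sv = forward_map(belief$mu_theta, model$L_tilde))
}

#' Internal model of the state dynamics
#'
#' The damped-oscillator dynamics the agent expects its own state to follow:
#' \deqn{f_1 = \mu_{\theta'}, \qquad
#'   f_2 = (\tilde K(\mu_{\theta_T} - \mu_\theta) -
#'          \tilde\phi\,\mu_{\theta'}) / \tilde m.}
#' In the resting condition (`mu_theta_T == mu_theta`) the elastic term
#' vanishes and `f_2` reduces to pure damping.
#'
#' @inheritParams expected_sensory
#' @return A named numeric vector `c(f1, f2)` (rad/s, rad/s^2).
#' @export
#' @examples
#' b <- set_target(belief_state(), pi / 3)
#' model_dynamics(b, model_params())  # f2 ~ 0.9076
model_dynamics <- function(belief, model) {
  stopifnot(inherits(belief, "belief_state"), inherits(model, "model_params"))
  muT <- if (belief$resting) belief$mu_theta else belief$mu_theta_T
  c(f1 = belief$mu_theta_prime,
    f2 = .f2(belief$mu_theta, belief$mu_theta_prime, muT, model))
}

.f2 <- function(mu, mup, muT, model) {
  (model$K_tilde * (muT - mu) - model$phi_tilde * mup) / model$m_tilde
}

#' Set the reaching target
#'
#' Fixes the desired joint angle, turning the attractor on and leaving the
#' resting condition: from the next loop step onward the attractor no longer
#' tracks the current state estimate. The target is given directly as a joint
#' angle (the configuration for which the hand is on the goal location);
#' inverting the forward kinematics from a Cartesian goal is out of scope.
#'
#' @param belief A [belief_state()].
#' @param theta_T Desired joint angle (rad).
#' @return The belief with `mu_theta_T = theta_T` and `resting = FALSE`; all
#'   other fields unchanged. Idempotent for a repeated identical target.
#' @export
set_target <- function(belief, theta_T) {
  stopifnot(inherits(belief, "belief_state"),
            "theta_T must be finite" = is_scalar_finite(theta_T))
  belief$mu_theta_T <- theta_T
  belief$resting <- FALSE
  belief
}
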