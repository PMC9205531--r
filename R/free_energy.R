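#' Gradient-descent gains
#'
#' Rate constants that put free-energy minimization for perception and for
#' action on timescales compatible with the arm's intrinsic dynamics. `k_mu`
#' holds one gain per belief order (angle, velocity, acceleration); `k_A`
#' holds the gains on the proprioceptive and visual routes to action. Setting
#' `k_A[2] = 0` models an agent whose movements cannot affect the visual hand
#' (as when the seen hand is a static fake one).
#'
#' @param k_mu Numeric triple of perceptual gains, non-negative.
#' @param k_A Numeric pair of action gains `c(prop, vis)`, non-negative.
#' @return An object of class `aif_gains`.
#' @export
gains <- function(k_mu = c(0.1, 0.01, 0.001), k_A = c(0.3, 0.3)) {
  stopifnot(
    "k_mu must be three non-negative numbers" =
      is.numeric(k_mu) && length(k_mu) == 3L && all(is.finite(k_mu)) && all(k_mu >= 0),
    "k_A must be two non-negative numbers" =
      is.numeric(k_A) && length(k_A) == 2L && all(is.finite(k_A)) && all(k_A >= 0)
  )
  structure(list(k_mu = unname(k_mu), k_A = unname(k_A)), class = "aif_gains")
}

#' Prediction errors at one step
#'
#' Computes the discrepancies that drive both inference and action:
#' * `eps_p = s_p - mu_theta` — proprioceptive sensory error (rad);
#' * `eps_v = s_v - g(mu_theta)` — visual sensory error, Cartesian pair (m);
#' * `eps_m1 = mu_theta_prime - f1` — first-order model error, identically 0
#'   because `f1` is defined as `mu_theta_prime`;
#' * `eps_m2 = mu_theta_dprime - f2` — second-order model error (rad/s^2),
#'   the signature of intentional movement: it is non-zero only when the
#'   attractor pulls the expected dynamics away from the inferred state.
#'
#' @param sample A `sensory_sample` from [sample_sensory()].
#' @param belief A [belief_state()].
#' @param model A [model_params()].
#' @return An object of class `error_bundle` with fields `eps_p`, `eps_v`
#'   (named `c(x, y)`), `eps_m1`, `eps_m2`.
#' @export
prediction_errors <- function(sample, belief, model) {
  stopifnot(inherits(sample, "sensory_sample"),
            inherits(belief, "belief_state"),
            inherits(model, "model_params"))
  muT <- if (belief$resting) belief$mu_theta else belief$mu_theta_T
  e <- .errors(sample$s_p, sample$s_v[[1L]], sample$s_v[[2L]],
               belief$mu_theta, belief$mu_theta_prime,
               belief$mu_theta_dprime, muT, model)
  structure(list(eps_p = e$eps_p, eps_v = c(x = e$eps_vx, y = e$eps_vy),
                 eps_m1 = 0, eps_m2 = e$eps_m2),
            class = "error_bundle")
}

.errors <- function(s_p, s_vx, s_vy, mu, mup, mupp, muT, model) {
  list(eps_p = s_p - mu,
       eps_vx = s_vx - model$L_tilde * sin(mu),
       eps_vy = s_vy - model$L_tilde * cos(mu),
       eps_m2 = mupp - .f2(mu, mup, muT, model))
}

#' Laplace-approximated variational free energy
#'
#' The precision-weighted sum of squared prediction errors (up to an additive
#' constant that does not depend on the belief or the action and is dropped):
#' \deqn{F = \tfrac12\left[\frac{\varepsilon_p^2}{\tilde\Sigma_{sp}}
#'   + \frac{\lVert\varepsilon_v\rVert^2}{\tilde\Sigma_{sv}}
#'   + \frac{\varepsilon_{m1}^2}{\Sigma_{\mu'}}
#'   + \frac{\varepsilon_{m2}^2}{\Sigma_{\mu''}}\right].}
#' Both Cartesian components of the visual error share the single expected
#' visual noise. `F >= 0`, with equality iff every error vanishes.
#'
#' @param errors An `error_bundle` from [prediction_errors()].
#' @param model A [model_params()] (supplies the precision weights; the
#'   constructor enforces strictly positive values).
#' @return Scalar free energy (nats, up to an additive constant).
#' @export
#' @examples
#' m <- model_params()
#' e <- structure(list(eps_p = 0.1, eps_v = c(x = 0, y = 0),
#'                     eps_m1 = 0, eps_m2 = 0), class = "error_bundle")
#' free_energy(e, m)  # 0.5 * 0.01 / 0.1 = 0.05
free_energy <- function(errors, model) {
  stopifnot(inherits(errors, "error_bundle"), inherits(model, "model_params"))
  0.5 * (errors$eps_p^2 / model$sigma_sp +
           sum(errors$eps_v^2) / model$sigma_sv +
           errors$eps_m1^2 / model$sigma_mu1 +
           errors$eps_m2^2 / model$sigma_mu2)
}

#' Free-energy gradient with respect to the belief
#'
#' Analytic partial derivatives of [free_energy()] with respect to the
#' inferred angle and velocity. The angle gradient carries the sensory terms
#' (proprioceptive directly, visual through the forward-map Jacobian) and the
#' model term through the attractor stiffness
#' (`d f2 / d mu_theta = -K_tilde / m_tilde`); the velocity gradient carries
#' only the model term through the internal damping
#' (`d f2 / d mu_theta_prime = -phi_tilde / m_tilde`), since the first-order
#' model error is identically zero. The third component, the derivative with
#' respect to the inferred acceleration, is `eps_m2 / sigma_mu2`.
#'
#' These expressions are verified against central finite differences of
#' [free_energy()] in the package's test suite.
#'
#' @inheritParams prediction_errors
#' @return Named numeric vector
#'   `c(d_mu_theta, d_mu_theta_prime, d_mu_theta_dprime)`.
#' @export
grad_belief <- function(sample, belief, model) {
  stopifnot(inherits(sample, "sensory_sample"),
            inherits(belief, "belief_state"),
            inherits(model, "model_params"))
  muT <- if (belief$resting) belief$mu_theta else belief$mu_theta_T
  g <- .grad_belief(sample$s_p, sample$s_v[[1L]], sample$s_v[[2L]],
                    belief$mu_theta, belief$mu_theta_prime,
                    belief$mu_theta_dprime, muT, model)
  c(d_mu_theta = g[[1L]], d_mu_theta_prime = g[[2L]],
    d_mu_theta_dprime = g[[3L]])
}

.grad_belief <- function(s_p, s_vx, s_vy, mu, mup, mupp, muT, model) {
  e <- .errors(s_p, s_vx, s_vy, mu, mup, mupp, muT, model)
  jx <- model$L_tilde * cos(mu)
  jy <- -model$L_tilde * sin(mu)
  em2_w <- e$eps_m2 / model$sigma_mu2
  d_mu <- -e$eps_p / model$sigma_sp -
    (e$eps_vx * jx + e$eps_vy * jy) / model$sigma_sv +
    em2_w * (model$K_tilde / model$m_tilde)
  d_mup <- em2_w * (model$phi_tilde / model$m_tilde)
  list(d_mu, d_mup, em2_w)
}

#' Free-energy gradient with respect to action, by sensory channel
#'
#' Action is not represented in the generative model, so the gradient is taken
#' through the assumed sensitivity of sensations to action. The proprioceptive
#' route uses the reflex-arc constant obtained by inverting the internal
#' dynamics at its equilibrium, `d s_p / d A = -m_tilde / K_tilde`; the visual
#' route chains the same constant through the forward-map Jacobian at the
#' inferred angle. The two components are returned separately so each can be
#' scaled by its own action gain and logged:
#' \deqn{\partial F/\partial A =
#'   \underbrace{\frac{\varepsilon_p}{\tilde\Sigma_{sp}}
#'     \left(-\frac{\tilde m}{\tilde K}\right)}_{\mathrm{prop}} +
#'   \underbrace{\frac{\varepsilon_v^\top g'(\mu_\theta)}{\tilde\Sigma_{sv}}
#'     \left(-\frac{\tilde m}{\tilde K}\right)}_{\mathrm{vis}}.}
#'
#' @inheritParams prediction_errors
#' @return Named numeric vector `c(prop, vis)`.
#' @export
#' @examples
#' # eps_p = 0.1 with defaults: 0.1 / 0.1 * (-1.5 / 1.3) = -1.1538
grad_action <- function(sample, belief, model) {
  stopifnot(inherits(sample, "sensory_sample"),
            inherits(belief, "belief_state"),
            inherits(model, "model_params"))
  muT <- if (belief$resting) belief$mu_theta else belief$mu_theta_T
  g <- .grad_action(sample$s_p, sample$s_v[[1L]], sample$s_v[[2L]],
                    belief$mu_theta, belief$mu_theta_prime,
                    belief$mu_theta_dprime, muT, model)
  c(prop = g[[1L]], vis = g[[2L]])
}

.grad_action <- function(s_p, s_vx, s_vy, mu, mup, mupp, muT, model) {
  e <- .errors(s_p, s_vx, s_vy, mu, mup, mupp, muT, model)
  reflex <- -model$m_tilde / model$K_tilde
  jx <- model$L_tilde * cos(mu)
  jy <- -model$L_tilde * sin(mu)
  list(e$eps_p / model$sigma_sp * reflex,
       (e$eps_vx * jx + e$eps_vy * jy) / model$sigma_sv * reflex)
}
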