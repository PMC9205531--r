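#' Scenario builders for the three study conditions
#'
#' Each builder returns a complete, runnable configuration (`aif_scenario`):
#' the physical arm, the agent's generative model, the gradient gains, the
#' visual source regime, the event schedule and the loop settings. The
#' defaults reproduce the study conditions exactly; the arguments exist so a
#' user can explore precision or gain manipulations without editing code.
#'
#' * `scenario_reach()`: visually guided reaching with no multisensory
#'   conflict. The agent starts at `theta = 0`, the target joint angle
#'   `theta_T = pi/3` is disclosed at `t_T = 3` s, and actions minimize both
#'   proprioceptive and visual errors (`k_A = c(0.3, 0.3)`).
#' * `scenario_rhi()`: the rubber hand illusion. No motor target is ever set
#'   (the agent rests throughout); at `t_onset = 3` s the view of the real
#'   hand is replaced instantaneously by a static fake hand at `pi/3`. The
#'   agent cannot move the fake hand, so the visual route to action is off
#'   (`k_A_v = 0`), and the fake hand is trusted less than own-hand vision
#'   (`sigma_sv = 0.07`), which also makes the illusion build up gradually.
#' * `scenario_virtual_reach()`: reaching while embodying a virtual arm whose
#'   velocity is the real arm's velocity times `gain` (1.3 by default). The
#'   two arms start co-located; everything else matches `scenario_reach()`.
#' * `scenario_control_prop_only()`: control variant of either reaching
#'   scenario with action driven by proprioception only
#'   (`k_A = c(0.6, 0)`).
#'
#' @param theta_T Target joint angle (rad).
#' @param t_T Target disclosure time (s).
#' @param sigma_sp,sigma_sv Expected sensory noise SDs of the agent's model.
#' @param k_A_p,k_A_v Action gains on the proprioceptive and visual routes.
#' @param t_onset Illusion onset time (s), `scenario_rhi()` only.
#' @param fake_theta Fake-hand joint angle (rad), `scenario_rhi()` only.
#' @param gain Velocity gain of the virtual arm, positive.
#' @param base Which scenario the proprioception-only control modifies.
#' @param t_sim,dt,sigma_acc Loop settings passed to [loop_config()].
#'
#' @return An object of class `aif_scenario`.
#' @seealso [run_simulation()], [sweep_velocity_gains()]
#' @name scenarios
NULL

.new_scenario <- function(name, theta0, theta_vr0, source, events,
                          sigma_sp, sigma_sv, k_A, t_sim, dt, sigma_acc) {
  structure(list(
    name = name,
    theta0 = theta0,
    theta_vr0 = theta_vr0,
    process = process_params(),
    model = model_params(sigma_sp = sigma_sp, sigma_sv = sigma_sv),
    gains = gains(k_A = k_A),
    source = source,
    events = events,
    loop = loop_config(t_sim = t_sim, dt = dt, sigma_acc = sigma_acc)
  ), class = "aif_scenario")
}

#' @rdname scenarios
#' @export
scenario_reach <- function(theta_T = pi / 3, t_T = 3, sigma_sp = 0.1,
                           sigma_sv = 0.01, k_A_p = 0.3, k_A_v = 0.3,
                           t_sim = 20, dt = 0.01, sigma_acc = 1e-3) {
  .new_scenario("reach", theta0 = 0, theta_vr0 = NULL,
                source = visual_source("real_hand"),
                events = list(target = list(time = t_T, theta = theta_T),
                              illusion = NULL),
                sigma_sp = sigma_sp, sigma_sv = sigma_sv,
                k_A = c(k_A_p, k_A_v),
                t_sim = t_sim, dt = dt, sigma_acc = sigma_acc)
}

#' @rdname scenarios
#' @export
scenario_rhi <- function(fake_theta = pi / 3, t_onset = 3, sigma_sp = 0.1,
                         sigma_sv = 0.07, k_A_p = 0.3, k_A_v = 0,
                         t_sim = 20, dt = 0.01, sigma_acc = 1e-3) {
  .new_scenario("rhi", theta0 = 0, theta_vr0 = NULL,
                source = visual_source("static_fake", fake_theta = fake_theta),
                events = list(target = NULL,
                              illusion = list(time = t_onset)),
                sigma_sp = sigma_sp, sigma_sv = sigma_sv,
                k_A = c(k_A_p, k_A_v),
                t_sim = t_sim, dt = dt, sigma_acc = sigma_acc)
}

#' @rdname scenarios
#' @export
scenario_virtual_reach <- function(gain = 1.3, theta_T = pi / 3, t_T = 3,
                                   sigma_sp = 0.1, sigma_sv = 0.01,
                                   k_A_p = 0.3, k_A_v = 0.3,
                                   t_sim = 20, dt = 0.01, sigma_acc = 1e-3) {
  if (!is_scalar_finite(gain) || gain <= 0)
    stop("gain must be a positive finite number", call. = FALSE)
  .new_scenario("virtual_reach", theta0 = 0, theta_vr0 = 0,
                source = visual_source("gained_virtual", velocity_gain = gain),
                events = list(target = list(time = t_T, theta = theta_T),
                              illusion = NULL),
                sigma_sp = sigma_sp, sigma_sv = sigma_sv,
                k_A = c(k_A_p, k_A_v),
                t_sim = t_sim, dt = dt, sigma_acc = sigma_acc)
}

#' @rdname scenarios
#' @export
scenario_control_prop_only <- function(base = c("reach", "virtual_reach"),
                                       gain = 1.3, ...) {
  base <- match.arg(base)
  sc <- switch(base,
               reach = scenario_reach(k_A_p = 0.6, k_A_v = 0, ...),
               virtual_reach = scenario_virtual_reach(gain = gain, k_A_p = 0.6,
                                                      k_A_v = 0, ...))
  sc$name <- paste0(base, "_prop_only")
  sc
}

#' Sweep the virtual-arm velocity gain
#'
#' Runs the virtual-reach scenario once per gain value with a common seed and
#' returns the trajectories, ready for the velocity-overlay comparison: real
#' velocity profiles separate clearly across gains while the inferred
#' velocities barely differ.
#'
#' @param gain_values Numeric vector of positive velocity gains.
#' @param seed Seed shared by all runs.
#' @param ... Further arguments passed to [scenario_virtual_reach()].
#' @return A named list of `aif_trajectory` objects (names are the gain
#'   values), with class `aif_gain_sweep` and the gains in attribute
#'   `gain_values`.
#' @export
sweep_velocity_gains <- function(gain_values = c(0.7, 0.85, 1, 1.3, 1.5),
                                 seed = 1L, ...) {
  stopifnot(is.numeric(gain_values), length(gain_values) >= 1L,
            all(is.finite(gain_values)), all(gain_values > 0))
  runs <- lapply(gain_values, function(g) {
    run_simulation(scenario_virtual_reach(gain = g, ...), seed = seed)
  })
  names(runs) <- format(gain_values)
  structure(runs, gain_values = gain_values, class = "aif_gain_sweep")
}

#' @export
print.aif_scenario <- function(x, ...) {
  cat("<aif_scenario>", x$name, "\n")
  cat("  visual source:", x$source$mode,
      if (!is.null(x$source$velocity_gain))
        sprintf("(gain %g)", x$source$velocity_gain) else "",
      if (!is.null(x$source$fake_theta))
        sprintf("(fake hand at %.4g rad)", x$source$fake_theta) else "", "\n")
  if (!is.null(x$events$target))
    cat(sprintf("  target: %.4g rad at t = %g s\n",
                x$events$target$theta, x$events$target$time))
  if (!is.null(x$events$illusion))
    cat(sprintf("  illusion onset at t = %g s\n", x$events$illusion$time))
  cat(sprintf("  model noise: sigma_sp = %g, sigma_sv = %g; k_A = [%g, %g]\n",
              x$model$sigma_sp, x$model$sigma_sv,
              x$gains$k_A[1], x$gains$k_A[2]))
  cat(sprintf("  loop: t_sim = %g s, dt = %g s\n", x$loop$t_sim, x$loop$dt))
  invisible(x)
}
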