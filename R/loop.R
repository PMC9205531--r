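#' Integration settings of the perception-action loop
#'
#' @param t_sim Total simulated duration (s).
#' @param dt Euler step (s). The loop runs `N = round(t_sim / dt)` steps.
#' @param sigma_acc Standard deviation of the random fluctuation that drives
#'   the inferred-acceleration order (per sqrt-second; entered as an
#'   Euler-Maruyama term `sqrt(dt) * sigma_acc * N(0,1)`). The inferred
#'   acceleration has no deterministic drive of its own beyond the
#'   free-energy gradient, so its evolution is modelled as these small
#'   fluctuations.
#' @param divergence_bound Abort threshold (rad) on `|theta|` and
#'   `|mu_theta|`; exceeding it raises a classed error
#'   (`activereach_divergence`) instead of silently producing garbage.
#'
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(t_sim = 20, dt = 0.01, sigma_acc = 1e-3,
                        divergence_bound = 10) {
  stopifnot(
    "t_sim must be positive" = is_scalar_finite(t_sim) && t_sim > 0,
    "dt must be positive" = is_scalar_finite(dt) && dt > 0 && dt <= t_sim,
    "sigma_acc must be >= 0" = is_scalar_finite(sigma_acc) && sigma_acc >= 0,
    "divergence_bound must be positive" =
      is_scalar_finite(divergence_bound) && divergence_bound > 0
  )
  n <- round(t_sim / dt)
  if (abs(n * dt - t_sim) > 1e-9)
    stop("t_sim must be an integer multiple of dt", call. = FALSE)
  structure(list(t_sim = t_sim, dt = dt, n_steps = as.integer(n),
                 sigma_acc = sigma_acc, divergence_bound = divergence_bound),
            class = "loop_config")
}

# One full iteration of the coupled perception-action loop, on scalars.
# Order within the step: (1) belief gradient descent (shifted by the
# generalized-coordinate flow), (2) action update, (3) world update with the
# new action, (4) new sensory sample for the next iteration. Returns the
# updated state plus the diagnostics evaluated *before* the update (the
# quantities that actually drove it).
.loop_step <- function(th, thp, thvr, mu, mup, mupp, muT, resting, A,
                       s_p, s_vx, s_vy, process, model, gns, source, dt,
                       sigma_acc) {
  if (resting) muT <- mu
  e <- .errors(s_p, s_vx, s_vy, mu, mup, mupp, muT, model)
  Fval <- 0.5 * (e$eps_p^2 / model$sigma_sp +
                   (e$eps_vx^2 + e$eps_vy^2) / model$sigma_sv +
                   e$eps_m2^2 / model$sigma_mu2)
  g <- .grad_belief(s_p, s_vx, s_vy, mu, mup, mupp, muT, model)
  a <- .grad_action(s_p, s_vx, s_vy, mu, mup, mupp, muT, model)
  fluct <- if (sigma_acc > 0) sqrt(dt) * sigma_acc * stats::rnorm(1L) else 0
  mu_n <- mu + dt * (mup - gns$k_mu[1L] * g[[1L]])
  mup_n <- mup + dt * (mupp - gns$k_mu[2L] * g[[2L]])
  mupp_n <- mupp + dt * (-gns$k_mu[3L] * g[[3L]]) + fluct
  # Descend F through the physical action-to-sensation sensitivity: a positive
  # angular acceleration raises the sensed angle, so the increment takes the
  # opposite sign of the reflex-arc-signed gradient components.
  A_n <- A + dt * (gns$k_A[1L] * a[[1L]] + gns$k_A[2L] * a[[2L]])
  st <- .step_arm(th, thp, thvr, A_n, process, source, dt)
  s_n <- .sample_sensory(st[[1L]], st[[3L]], process, source)
  list(theta = st[[1L]], theta_prime = st[[2L]], theta_vr = st[[3L]],
       mu_theta = mu_n, mu_theta_prime = mup_n, mu_theta_dprime = mupp_n,
       mu_theta_T = muT, A = A_n,
       s_p = s_n[[1L]], s_vx = s_n[[2L]], s_vy = s_n[[3L]],
       eps_p = e$eps_p, eps_v_norm = sqrt(e$eps_vx^2 + e$eps_vy^2),
       eps_m2 = e$eps_m2, F = Fval, a_prop = a[[1L]], a_vis = a[[2L]])
}

#' One step of the perception-action loop
#'
#' Advances the coupled system by one Euler step of length `dt`, in the fixed
#' order: belief update (gradient descent on free energy, shifted by the
#' generalized-coordinate flow), action update, world update with the new
#' action, and a fresh sensory sample for the next iteration. While the belief
#' is in the resting condition the attractor is re-assigned to the current
#' angle estimate before the gradients are evaluated.
#'
#' Noise (sensory and the inferred-acceleration fluctuation) is drawn from the
#' current RNG stream; seed it once per run.
#'
#' @param world A [system_state()].
#' @param belief A [belief_state()].
#' @param action Current action A (rad/s^2).
#' @param sample The `sensory_sample` observed from the previous world state.
#' @param process A [process_params()].
#' @param model A [model_params()].
#' @param gains_ An [gains()] object.
#' @param source A [visual_source()].
#' @param dt Step length (s).
#' @param sigma_acc Fluctuation SD for the inferred acceleration (see
#'   [loop_config()]).
#'
#' @return A list with the updated `world`, `belief`, `action`, `sample`, and
#'   a `diagnostics` list (pre-update prediction errors, free energy, and the
#'   two unweighted action-gradient components).
#' @export
loop_step <- function(world, belief, action, sample, process, model, gains_,
                      source, dt, sigma_acc = 0) {
  stopifnot(inherits(world, "system_state"), inherits(belief, "belief_state"),
            inherits(sample, "sensory_sample"),
            inherits(process, "process_params"),
            inherits(model, "model_params"), inherits(gains_, "aif_gains"),
            inherits(source, "visual_source"),
            is_scalar_finite(action), is_scalar_finite(dt), dt > 0)
  r <- .loop_step(world$theta, world$theta_prime, world$theta_vr,
                  belief$mu_theta, belief$mu_theta_prime,
                  belief$mu_theta_dprime, belief$mu_theta_T, belief$resting,
                  action, sample$s_p, sample$s_v[[1L]], sample$s_v[[2L]],
                  process, model, gains_, source, dt, sigma_acc)
  list(
    world = system_state(r$theta, r$theta_prime, r$theta_vr),
    belief = belief_state(r$mu_theta, r$mu_theta_prime, r$mu_theta_dprime,
                          mu_theta_T = r$mu_theta_T, resting = belief$resting),
    action = r$A,
    sample = structure(list(s_p = r$s_p, s_v = c(x = r$s_vx, y = r$s_vy)),
                       class = "sensory_sample"),
    diagnostics = list(eps_p = r$eps_p, eps_v_norm = r$eps_v_norm,
                       eps_m2 = r$eps_m2, F = r$F,
                       a_prop = r$a_prop, a_vis = r$a_vis)
  )
}

#' Run a full scenario simulation
#'
#' Iterates the perception-action loop for the whole duration of a scenario,
#' applying its scheduled events (target disclosure, illusion onset) at their
#' times. The run is deterministic given `seed`. The initial belief equals the
#' initial true state with zero derivatives, in the resting condition; the
#' initial action is 0.
#'
#' @param scenario An `aif_scenario` from one of the scenario builders
#'   ([scenario_reach()], [scenario_rhi()], [scenario_virtual_reach()],
#'   [scenario_control_prop_only()]).
#' @param seed Integer seed for all randomness of the run.
#' @param t_sim,dt Optional overrides of the scenario's loop settings.
#'
#' @return An `aif_trajectory`: a data frame with one row per time point
#'   (`n_steps + 1` rows including the initial conditions) and columns `t`,
#'   `theta`, `theta_prime`, `theta_vr`, `mu_theta`, `mu_theta_prime`,
#'   `mu_theta_dprime`, `mu_theta_T`, `A`, `a_prop`, `a_vis`, `eps_p`,
#'   `eps_v_norm`, `eps_m2`, `F`. Each row's errors, free energy and action
#'   components are the instantaneous values at that time (the quantities
#'   that drove the step taken from it). The scenario and seed are attached
#'   as attributes `scenario` and `seed`.
#' @export
#' @examples
#' traj <- run_simulation(scenario_reach(), seed = 1, t_sim = 2)
#' tail(traj$theta, 1)
run_simulation <- function(scenario, seed = 1L, t_sim = NULL, dt = NULL) {
  stopifnot(inherits(scenario, "aif_scenario"))
  lc <- scenario$loop
  if (!is.null(t_sim) || !is.null(dt)) {
    lc <- loop_config(t_sim = t_sim %||% lc$t_sim, dt = dt %||% lc$dt,
                      sigma_acc = lc$sigma_acc,
                      divergence_bound = lc$divergence_bound)
  }
  process <- scenario$process
  model <- scenario$model
  gns <- scenario$gains
  source <- scenario$source
  ev <- scenario$events
  n <- lc$n_steps
  dt_ <- lc$dt

  set.seed(as.integer(seed))

  th <- scenario$theta0
  thp <- 0
  thvr <- if (!is.null(ev$illusion) || identical(source$mode, "gained_virtual"))
    scenario$theta_vr0 else NULL
  mu <- th; mup <- 0; mupp <- 0; muT <- th
  resting <- TRUE
  A <- 0
  # the illusion event switches the visual regime at its scheduled time;
  # before it the agent sees the real hand
  active_source <- if (!is.null(ev$illusion))
    visual_source("real_hand") else source
  s <- .sample_sensory(th, thvr, process, active_source)

  cols <- c("t", "theta", "theta_prime", "theta_vr", "mu_theta",
            "mu_theta_prime", "mu_theta_dprime", "mu_theta_T", "A",
            "a_prop", "a_vis", "eps_p", "eps_v_norm", "eps_m2", "F")
  log <- matrix(NA_real_, nrow = n + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (i in seq_len(n)) {
    t_now <- (i - 1L) * dt_
    if (!is.null(ev$target) && resting && t_now >= ev$target$time - 1e-12) {
      muT <- ev$target$theta
      resting <- FALSE
    }
    if (!is.null(ev$illusion) && !identical(active_source, source) &&
        t_now >= ev$illusion$time - 1e-12) {
      active_source <- source
    }
    r <- .loop_step(th, thp, thvr, mu, mup, mupp, muT, resting, A,
                    s[[1L]], s[[2L]], s[[3L]], process, model, gns,
                    active_source, dt_, lc$sigma_acc)
    log[i, ] <- c(t_now, th, thp, thvr %||% NA_real_, mu, mup, mupp,
                  r$mu_theta_T, A, r$a_prop, r$a_vis, r$eps_p, r$eps_v_norm,
                  r$eps_m2, r$F)
    th <- r$theta; thp <- r$theta_prime; thvr <- r$theta_vr
    mu <- r$mu_theta; mup <- r$mu_theta_prime; mupp <- r$mu_theta_dprime
    A <- r$A
    s <- list(r$s_p, r$s_vx, r$s_vy)
    if (abs(th) > lc$divergence_bound || abs(mu) > lc$divergence_bound) {
      cond <- structure(
        class = c("activereach_divergence", "error", "condition"),
        list(message = sprintf(
          "simulation diverged at t = %.2f s (|theta| = %.2f, |mu_theta| = %.2f, bound = %g rad)",
          i * dt_, abs(th), abs(mu), lc$divergence_bound), call = NULL))
      stop(cond)
    }
  }
  # closing snapshot with the instantaneous diagnostics at the final state
  if (resting) muT <- mu
  e <- .errors(s[[1L]], s[[2L]], s[[3L]], mu, mup, mupp, muT, model)
  a <- .grad_action(s[[1L]], s[[2L]], s[[3L]], mu, mup, mupp, muT, model)
  Fval <- 0.5 * (e$eps_p^2 / model$sigma_sp +
                   (e$eps_vx^2 + e$eps_vy^2) / model$sigma_sv +
                   e$eps_m2^2 / model$sigma_mu2)
  log[n + 1L, ] <- c(n * dt_, th, thp, thvr %||% NA_real_, mu, mup, mupp, muT,
                     A, a[[1L]], a[[2L]], e$eps_p,
                     sqrt(e$eps_vx^2 + e$eps_vy^2), e$eps_m2, Fval)

  traj <- as.data.frame(log)
  attr(traj, "scenario") <- scenario
  attr(traj, "seed") <- as.integer(seed)
  attr(traj, "loop") <- lc
  class(traj) <- c("aif_trajectory", "data.frame")
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
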