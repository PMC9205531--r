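# Shared test utilities: a finite-difference oracle for the free-energy
# gradients and generators for random model configurations.

make_sample <- function(s_p, s_vx, s_vy) {
  structure(list(s_p = s_p, s_v = c(x = s_vx, y = s_vy)),
            class = "sensory_sample")
}

# random (sample, belief, model) triple; beliefs are non-resting so the
# attractor is a free coordinate and F is an ordinary function of the belief
rand_config <- function() {
  model <- model_params(
    sigma_sp = runif(1, 0.05, 0.3),
    sigma_sv = runif(1, 0.005, 0.1),
    sigma_mu2 = runif(1, 0.05, 0.3)
  )
  belief <- belief_state(
    mu_theta = runif(1, -1.2, 1.2),
    mu_theta_prime = runif(1, -2, 2),
    mu_theta_dprime = runif(1, -3, 3),
    mu_theta_T = runif(1, -1.2, 1.2),
    resting = FALSE
  )
  sample <- make_sample(
    belief$mu_theta + runif(1, -0.5, 0.5),
    runif(1, -0.5, 0.5),
    runif(1, -0.1, 0.5)
  )
  list(sample = sample, belief = belief, model = model)
}

F_of <- function(sample, belief, model) {
  free_energy(prediction_errors(sample, belief, model), model)
}

# central finite differences of F with respect to one belief coordinate
fd_belief <- function(sample, belief, model, coord, h = 1e-5) {
  up <- down <- belief
  up[[coord]] <- up[[coord]] + h
  down[[coord]] <- down[[coord]] - h
  (F_of(sample, up, model) - F_of(sample, down, model)) / (2 * h)
}

# central finite differences of F through the assumed action-to-sensation
# sensitivities: the reflex-arc constant for proprioception, chained through
# the forward-map Jacobian for vision
fd_action <- function(sample, belief, model, channel = c("prop", "vis"),
                      h = 1e-5) {
  channel <- match.arg(channel)
  reflex <- -model$m_tilde / model$K_tilde
  shift <- function(da) {
    s <- sample
    if (channel == "prop") {
      s$s_p <- s$s_p + reflex * da
    } else {
      j <- forward_jacobian(belief$mu_theta, model$L_tilde)
      s$s_v <- s$s_v + j * reflex * da
    }
    s
  }
  (F_of(shift(h), belief, model) - F_of(shift(-h), belief, model)) / (2 * h)
}

rel_err <- function(got, want) abs(got - want) / pmax(abs(want), 1e-8)

# scenario variants with all randomness switched off
noise_free <- function(sc) {
  sc$process <- process_params(sigma_p = 0, sigma_v = 0)
  sc$loop <- loop_config(t_sim = sc$loop$t_sim, dt = sc$loop$dt,
                         sigma_acc = 0,
                         divergence_bound = sc$loop$divergence_bound)
  sc
}

# a scenario that never leaves the resting condition (target never disclosed)
resting_scenario <- function(theta0 = 0, t_sim = 20) {
  sc <- scenario_reach(t_T = 1e6, t_sim = t_sim)
  sc$theta0 <- theta0
  sc
}
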