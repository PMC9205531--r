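test_that("a noise-free resting agent is an exact fixed point of the loop", {
  for (th0 in c(0, 0.3)) {
    traj <- run_simulation(noise_free(resting_scenario(theta0 = th0)),
                           seed = 1)
    expect_equal(nrow(traj), 2001L)
    expect_lt(max(abs(traj$theta - th0)), 1e-10)
    expect_lt(max(abs(traj$theta_prime)), 1e-10)
    expect_lt(max(abs(traj$mu_theta - th0)), 1e-10)
    expect_lt(max(abs(traj$mu_theta_prime)), 1e-10)
    expect_lt(max(abs(traj$A)), 1e-10)
    expect_lt(max(traj$F), 1e-10)
  }
})

test_that("runs are deterministic given the seed and differ across seeds", {
  sc <- scenario_reach(t_sim = 4)
  a <- run_simulation(sc, seed = 5)
  b <- run_simulation(sc, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_simulation(sc, seed = 6)
  expect_false(identical(a$theta, c$theta))
  # different seeds agree on the broad outcome (noise-level variability only)
  expect_lt(abs(tail(a$theta, 1) - tail(c$theta, 1)), 0.2)
})

test_that("the trajectory log is complete: every time point, no gaps", {
  traj <- run_simulation(scenario_reach(t_sim = 2), seed = 1)
  expect_equal(traj$t, seq(0, 2, by = 0.01))
  core <- setdiff(names(traj), "theta_vr")
  expect_false(any(is.na(as.matrix(traj[core]))))
  expect_true(all(is.na(traj$theta_vr)))  # no virtual arm in plain reaching

  tv <- run_simulation(scenario_virtual_reach(t_sim = 2), seed = 1)
  expect_false(any(is.na(tv$theta_vr)))
})

test_that("one exported loop_step reproduces the internal integrator exactly", {
  sc <- scenario_reach()
  n_steps <- 5L
  traj <- run_simulation(sc, seed = 9, t_sim = n_steps * sc$loop$dt)

  set.seed(9L)
  world <- system_state(theta = sc$theta0)
  belief <- belief_state(mu_theta = sc$theta0)
  sample <- sample_sensory(world, sc$process, sc$source)
  action <- 0
  for (i in seq_len(n_steps)) {
    st <- loop_step(world, belief, action, sample, sc$process, sc$model,
                    sc$gains, sc$source, dt = sc$loop$dt,
                    sigma_acc = sc$loop$sigma_acc)
    world <- st$world; belief <- st$belief
    action <- st$action; sample <- st$sample
  }
  last <- traj[nrow(traj), ]
  expect_equal(world$theta, last$theta, tolerance = 1e-14)
  expect_equal(world$theta_prime, last$theta_prime, tolerance = 1e-14)
  expect_equal(belief$mu_theta, last$mu_theta, tolerance = 1e-14)
  expect_equal(belief$mu_theta_dprime, last$mu_theta_dprime,
               tolerance = 1e-14)
  expect_equal(action, last$A, tolerance = 1e-14)
})

test_that("with all noise off and no events, free energy stays at zero", {
  traj <- run_simulation(noise_free(resting_scenario(theta0 = 0.5, t_sim = 5)),
                         seed = 2)
  expect_identical(max(traj$F), 0)
  expect_identical(max(abs(traj$eps_p)), 0)
  expect_identical(max(traj$eps_v_norm), 0)
})

test_that("the divergence guard aborts with a classed, informative error", {
  sc <- scenario_reach(t_sim = 10)
  sc$loop <- loop_config(t_sim = 10, dt = 0.01, sigma_acc = 1e-3,
                         divergence_bound = 0.5)
  expect_error(run_simulation(sc, seed = 1),
               class = "activereach_divergence")
  expect_error(run_simulation(sc, seed = 1), "diverged")
})

test_that("halving the integration step barely changes the arrival time", {
  # arrival measured at the coarse 0.1-rad band, where the noise-free run
  # settles within the simulated horizon
  sc <- noise_free(scenario_reach())
  r1 <- reach_time(run_simulation(sc, seed = 1), tol = 0.1)
  r2 <- reach_time(run_simulation(sc, seed = 1, dt = 0.005), tol = 0.1)
  expect_false(is.na(r1) || is.na(r2))
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("the reaching scenario converges on the target angle", {
  traj <- run_simulation(scenario_reach(), seed = 1)
  # before disclosure the agent keeps its posture
  expect_lt(max(abs(traj$theta[traj$t < 3])), 0.1)
  # afterwards the hand closes most of the distance to pi/3
  expect_gt(tail(traj$theta, 1), pi / 3 - 0.1)
  expect_lt(tail(traj$theta, 1), pi / 3 + 0.1)
})
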