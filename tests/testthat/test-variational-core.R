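test_that("prediction errors vanish for a perfectly predicted sample", {
  m <- model_params()
  b <- belief_state(mu_theta = 0.6, resting = TRUE)
  s <- make_sample(0.6, forward_map(0.6)[["x"]], forward_map(0.6)[["y"]])
  e <- prediction_errors(s, b, m)
  expect_equal(e$eps_p, 0)
  expect_equal(unname(e$eps_v), c(0, 0))
  expect_identical(e$eps_m1, 0)
  expect_equal(e$eps_m2, 0)
})

test_that("a misplaced fake hand produces a purely visual conflict", {
  # belief and proprioception agree at 0 while vision reports pi/3
  m <- model_params()
  b <- belief_state(mu_theta = 0, resting = TRUE)
  fake <- forward_map(pi / 3)
  s <- make_sample(0, fake[["x"]], fake[["y"]])
  e <- prediction_errors(s, b, m)
  expect_equal(e$eps_p, 0)
  expect_equal(e$eps_v, forward_map(pi / 3) - forward_map(0))
})

test_that("the first-order model error is identically zero", {
  set.seed(11)
  for (i in 1:20) {
    cfg <- rand_config()
    expect_identical(prediction_errors(cfg$sample, cfg$belief,
                                       cfg$model)$eps_m1, 0)
  }
})

test_that("free energy is the stated precision-weighted quadratic form", {
  m <- model_params()
  zero <- structure(list(eps_p = 0, eps_v = c(x = 0, y = 0), eps_m1 = 0,
                         eps_m2 = 0), class = "error_bundle")
  expect_identical(free_energy(zero, m), 0)

  e <- zero; e$eps_p <- 0.1
  expect_equal(free_energy(e, m), 0.05, tolerance = 1e-15)

  # quadratic: doubling every error quadruples F
  set.seed(3)
  e <- structure(list(eps_p = rnorm(1), eps_v = c(x = rnorm(1), y = rnorm(1)),
                      eps_m1 = 0, eps_m2 = rnorm(1)), class = "error_bundle")
  e2 <- e
  e2$eps_p <- 2 * e$eps_p; e2$eps_v <- 2 * e$eps_v; e2$eps_m2 <- 2 * e$eps_m2
  expect_equal(free_energy(e2, m), 4 * free_energy(e, m), tolerance = 1e-12)
})

test_that("analytic belief gradients match the finite-difference oracle", {
  set.seed(101)
  for (i in 1:300) {
    cfg <- rand_config()
    g <- grad_belief(cfg$sample, cfg$belief, cfg$model)
    fd <- c(fd_belief(cfg$sample, cfg$belief, cfg$model, "mu_theta"),
            fd_belief(cfg$sample, cfg$belief, cfg$model, "mu_theta_prime"),
            fd_belief(cfg$sample, cfg$belief, cfg$model, "mu_theta_dprime"))
    expect_lt(max(rel_err(unname(g), fd)), 1e-6)
  }
})

test_that("analytic action gradients match the oracle through the assumed sensitivities", {
  set.seed(102)
  for (i in 1:300) {
    cfg <- rand_config()
    a <- grad_action(cfg$sample, cfg$belief, cfg$model)
    expect_lt(rel_err(a[["prop"]],
                      fd_action(cfg$sample, cfg$belief, cfg$model, "prop")),
              1e-6)
    expect_lt(rel_err(a[["vis"]],
                      fd_action(cfg$sample, cfg$belief, cfg$model, "vis")),
              1e-6)
  }
})

test_that("gradients carry the documented reference values and signs", {
  m <- model_params()
  # zero errors: stationary point
  b <- belief_state(mu_theta = 0.4, mu_theta_T = 0.4, resting = FALSE)
  s <- make_sample(0.4, forward_map(0.4)[["x"]], forward_map(0.4)[["y"]])
  expect_equal(unname(grad_belief(s, b, m)), c(0, 0, 0))
  expect_equal(unname(grad_action(s, b, m)), c(0, 0))

  # a pure proprioceptive error pulls the belief toward the sensed angle
  s2 <- make_sample(0.5, forward_map(0.4)[["x"]], forward_map(0.4)[["y"]])
  expect_lt(grad_belief(s2, b, m)[["d_mu_theta"]], 0)
  # ... and its action component is eps_p / sigma_sp times -m~/K~
  expect_equal(grad_action(s2, b, m)[["prop"]],
               (0.1 / 0.1) * (-1.5 / 1.3), tolerance = 1e-12)
  expect_equal(grad_action(s2, b, m)[["vis"]], 0)
})

test_that("with the visual channel switched off, F is invariant under joint translation", {
  m <- model_params(sigma_sv = 1e12)
  b <- belief_state(mu_theta = 0.3, mu_theta_prime = 0.5,
                    mu_theta_dprime = -0.2, mu_theta_T = 0.9,
                    resting = FALSE)
  s <- make_sample(0.45, 0.2, 0.4)
  shift <- 0.7
  b2 <- b
  b2$mu_theta <- b$mu_theta + shift
  b2$mu_theta_T <- b$mu_theta_T + shift
  s2 <- s; s2$s_p <- s$s_p + shift
  expect_equal(F_of(s2, b2, m), F_of(s, b, m), tolerance = 1e-9)
})

test_that("a small gradient step on the belief never increases F", {
  set.seed(103)
  eta <- 1e-5
  for (i in 1:50) {
    cfg <- rand_config()
    g <- grad_belief(cfg$sample, cfg$belief, cfg$model)
    b2 <- cfg$belief
    b2$mu_theta <- b2$mu_theta - eta * g[["d_mu_theta"]]
    b2$mu_theta_prime <- b2$mu_theta_prime - eta * g[["d_mu_theta_prime"]]
    b2$mu_theta_dprime <- b2$mu_theta_dprime - eta * g[["d_mu_theta_dprime"]]
    expect_lte(F_of(cfg$sample, b2, cfg$model),
               F_of(cfg$sample, cfg$belief, cfg$model) + 1e-12)
  }
})
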