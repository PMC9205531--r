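test_that("forward kinematics maps reference angles correctly", {
  expect_equal(forward_map(0, 0.45), c(x = 0, y = 0.45))
  expect_equal(forward_map(pi / 2, 0.45), c(x = 0.45, y = 0),
               tolerance = 1e-12)
  expect_equal(forward_map(pi / 3, 0.45),
               c(x = 0.3897114317029974, y = 0.225), tolerance = 1e-12)
  expect_error(forward_map(NaN), "finite")
  expect_error(forward_map(0.2, L = -1), "positive")
})

test_that("forward kinematics is injective on the workspace and its Jacobian is exact", {
  th <- seq(-pi / 2 + 0.01, pi / 2 - 0.01, length.out = 41)
  xy <- forward_map(th, 0.45)
  expect_false(any(duplicated(round(xy, 12))))
  h <- 1e-6
  for (a in c(-1.2, -0.3, 0, 0.5, 1.4)) {
    fd <- (forward_map(a + h, 0.45) - forward_map(a - h, 0.45)) / (2 * h)
    expect_equal(unname(forward_jacobian(a, 0.45)), unname(fd),
                 tolerance = 1e-8)
  }
})

test_that("arm dynamics: rest is a fixed point and damping follows the stated law", {
  p <- process_params()
  src <- visual_source("real_hand")
  st <- system_state(theta = 0.2, theta_prime = 0)
  st2 <- step_arm(st, A = 0, p, src, dt = 0.01)
  expect_identical(st2$theta, 0.2)
  expect_identical(st2$theta_prime, 0)

  # at theta_prime = 1 the damping acceleration is -phi/m = -4/1.5
  st <- system_state(theta = 0, theta_prime = 1)
  st2 <- step_arm(st, A = 0, p, src, dt = 0.01)
  expect_equal((st2$theta_prime - 1) / 0.01, -2.6666666666666665,
               tolerance = 1e-12)

  # odd symmetry: damping opposes motion in both directions
  stn <- step_arm(system_state(0, -1), A = 0, p, src, dt = 0.01)
  expect_equal(stn$theta_prime + 1, -(st2$theta_prime - 1), tolerance = 1e-12)
})

test_that("free damping dissipates velocity monotonically to zero", {
  p <- process_params()
  src <- visual_source("real_hand")
  st <- system_state(theta = 0, theta_prime = 1.5)
  v <- numeric(2000)
  for (i in 1:2000) {
    st <- step_arm(st, A = 0, p, src, dt = 0.01)
    v[i] <- st$theta_prime
  }
  # strictly decreasing until the velocity falls into the band where a
  # single Euler step overshoots zero (sublinear damping), bounded there on
  thr <- 2e-3
  small <- which(abs(v) < thr)[1]
  expect_false(is.na(small))
  expect_true(all(diff(abs(v[1:small])) < 0))
  expect_true(all(abs(v[small:2000]) < thr))
})

test_that("Euler stepping converges to a finer-step solution", {
  p <- process_params()
  src <- visual_source("real_hand")
  integrate_to <- function(dt, t_end = 1, A = 0.5) {
    st <- system_state(theta = 0, theta_prime = 0.8)
    for (i in seq_len(round(t_end / dt))) st <- step_arm(st, A, p, src, dt)
    st$theta
  }
  coarse <- integrate_to(0.01)
  fine <- integrate_to(0.001)
  expect_equal(coarse, fine, tolerance = 5e-3)
})

test_that("virtual arm advances at the velocity gain times the real velocity", {
  p <- process_params()
  src <- visual_source("gained_virtual", velocity_gain = 1.3)
  st <- system_state(theta = 0, theta_prime = 0.1, theta_vr = 0)
  st2 <- step_arm(st, A = 0, p, src, dt = 0.01)
  expect_equal(st2$theta_vr, 0.0013, tolerance = 1e-15)
  expect_equal(st2$theta - st$theta, 0.0010, tolerance = 1e-15)

  # cumulative: displacement of the virtual arm is exactly gain times the
  # real displacement under Euler stepping with matching initial angles
  st <- system_state(theta = 0.1, theta_prime = 0.6, theta_vr = 0.1)
  for (i in 1:500) st <- step_arm(st, A = 0.3 * sin(i / 50), p, src, 0.01)
  expect_equal(st$theta_vr - 0.1, 1.3 * (st$theta - 0.1), tolerance = 1e-12)
})

test_that("sensory sampling draws from the configured source and noise levels", {
  src <- visual_source("real_hand")
  p0 <- process_params(sigma_p = 0, sigma_v = 0)
  st <- system_state(theta = pi / 3)
  s <- sample_sensory(st, p0, src)
  expect_equal(s$s_p, pi / 3)
  expect_equal(s$s_v, forward_map(pi / 3, 0.45))

  # static fake hand: the visual channel reports the fake hand, not the arm
  fake <- visual_source("static_fake", fake_theta = pi / 3)
  s <- sample_sensory(system_state(theta = -0.4), p0, fake)
  expect_equal(s$s_v, forward_map(pi / 3, 0.45))
  expect_equal(s$s_p, -0.4)

  # gained-virtual: the visual channel reports the virtual arm angle
  gv <- visual_source("gained_virtual", velocity_gain = 1.3)
  s <- sample_sensory(system_state(theta = 0.1, theta_vr = 0.9), p0, gv)
  expect_equal(s$s_v, forward_map(0.9, 0.45))

  # noise SDs are recovered from repeated draws (3-SE band)
  set.seed(42)
  p <- process_params()
  n <- 1e4
  draws <- replicate(n, sample_sensory(st, p, src)$s_p)
  se_of_sd <- p$sigma_p / sqrt(2 * (n - 1))
  expect_lt(abs(sd(draws) - p$sigma_p), 3 * se_of_sd)
  vx <- replicate(n, sample_sensory(st, p, fake)$s_v[["x"]])
  expect_lt(abs(mean(vx) - forward_map(pi / 3, 0.45)[["x"]]),
            3 * p$sigma_v / sqrt(n))
})

test_that("constructors validate their domain constraints", {
  expect_error(process_params(L_arm = 0), "positive")
  expect_error(process_params(beta = 1.5), "beta")
  expect_error(process_params(sigma_v = -1), "sigma_v")
  expect_error(visual_source("static_fake"), "fake_theta")
  expect_error(visual_source("gained_virtual", velocity_gain = -2),
               "velocity_gain")
  expect_error(visual_source("real_hand", fake_theta = 1), "static_fake")
  expect_error(system_state(theta = Inf), "finite")
})
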