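test_that("Hill force normalization and passive behaviour", {
  p <- muscle_params("m", f_max = 1000, l_opt = 0.1, l_ts = 0.2)
  # fiber exactly at optimal length, isometric, full activation
  expect_equal(muscle_force(1, 0.3, 0, p), 1000, tolerance = 1e-9)
  expect_equal(muscle_force(0, 0.3, 0, p), 0, tolerance = 1e-12)
  # direct-formula oracle at a = 0.5, normalized length 1.1, zero velocity
  F <- muscle_force(0.5, 0.2 + 0.11, 0, p)
  F_ref <- 1000 * (0.5 * force_length(1.1) + force_passive(1.1))
  expect_equal(F, F_ref, tolerance = 1e-9)
  expect_true(all(muscle_force(c(0, 0.5, 1), 0.31, -0.05, p) >= 0))
  expect_error(muscle_force(0.5, 0.15, 0, p), "fiber length")
})

test_that("pennation reduces force through the cosine", {
  p <- muscle_params("m", 1000, 0.1, 0.2, pennation = 0.3)
  w <- 0.1 * sin(0.3)
  lmt <- 0.2 + sqrt(0.1^2 - w^2)  # fiber length exactly l_opt
  expect_equal(muscle_force(1, lmt, 0, p), 1000 * cos(asin(w / 0.1)),
               tolerance = 1e-6)
})

test_that("activation dynamics: rest, plateau, and first-order rise time", {
  p <- muscle_params("m", 1000, 0.1, 0.2, tau_act = 0.015, tau_deact = 0.05,
                     shape = 0)
  dt <- 1e-4
  n <- 3000
  expect_true(all(activation_dynamics(rep(0, n), p, dt, a0 = 0) == 0))
  a <- activation_dynamics(rep(1, n), p, dt, a0 = 0)
  expect_equal(a[n], 1, tolerance = 1e-6)
  # step response reaches 1 - 1/e at t = tau_act (bilinear rate = 1/tau_act
  # at u = 1); closed-form first-order oracle
  k632 <- round(0.015 / dt) + 1
  expect_equal(a[k632], 1 - exp(-1), tolerance = 2e-3)
  expect_error(activation_dynamics(rep(0, 10), p, -0.1), "dt")
  expect_error(muscle_params("m", 1000, 0.1, 0.2, tau_act = 0.06,
                             tau_deact = 0.05), "tau_act")
})

test_that("activation dynamics output is stable under time-grid refinement", {
  p <- muscle_params("m", 1000, 0.1, 0.2, shape = 1.2)
  t_end <- 1
  u_fun <- function(t) 0.5 + 0.4 * sin(2 * pi * t)
  a_coarse <- activation_dynamics(u_fun(seq(0, t_end, by = 2e-3)), p, 2e-3, a0 = 0.5)
  a_dense <- activation_dynamics(u_fun(seq(0, t_end, by = 1e-4)), p, 1e-4, a0 = 0.5)
  expect_lt(max(abs(a_coarse - a_dense[seq(1, length(a_dense), by = 20)])), 5e-3)
})

test_that("excitation inversion round-trips a smooth periodic activation", {
  p <- muscle_params("m", 1000, 0.1, 0.2, shape = 1.0)
  t_end <- 1.2; dt <- t_end / 200
  tt <- seq(0, t_end - dt, by = dt)
  # the decay rate stays within what the deactivation time constant allows,
  # so an exactly consistent excitation exists
  a_true <- 0.4 + 0.2 * sin(2 * pi * tt / t_end) + 0.05 * cos(4 * pi * tt / t_end)
  u <- gaitfes:::invert_activation_dynamics(a_true, p, dt)
  a_rec <- activation_dynamics(c(u, u), p, dt, a0 = u[1])[length(u) + seq_along(u)]
  expect_lt(max(abs(a_rec - a_true)), 0.01)
})
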