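test_that("free fall and supported standing are dynamically consistent", {
  sk <- test_skel
  q <- rep(0, 11); q[2] <- 1.0
  qdd <- rep(0, 11); qdd[2] <- -sk$gravity
  expect_lt(max(abs(skeleton_dynamics_residual(sk, q, rep(0, 11), qdd))), 1e-8)

  # standing: upward forces at both feet equal to half body weight each,
  # placed under the total centre of mass, balance gravity in the pelvis
  # translational equations
  bw <- sum(vapply(sk$segments, `[[`, 0, "mass")) * sk$gravity
  fk <- gaitfes:::fk_batched(sk, gaitfes:::as_coord_array(q))
  com_x <- sum(vapply(names(sk$segments), function(nm)
    sk$segments[[nm]]$mass * fk[[nm]]$cx[1, 1], 0)) / (bw / sk$gravity)
  loads <- lapply(c("foot_r", "foot_l"), function(seg) {
    # express the support point in the foot frame (theta = 0 pose)
    fx0 <- fk[[seg]]$ox[1, 1]; fy0 <- fk[[seg]]$oy[1, 1]
    list(segment = seg, px = com_x - fx0, py = -0.08 - 0 * fy0,
         fx = 0, fy = bw / 2)
  })
  r <- skeleton_dynamics_residual(sk, q, rep(0, 11), rep(0, 11),
                                  external_forces = loads)
  expect_lt(max(abs(r[1:3])) / bw, 1e-10)
})

test_that("dynamics residual matches a numeric Lagrangian oracle", {
  sk <- test_skel
  set.seed(7)
  for (rep_i in 1:2) {
    q <- runif(11, -0.4, 0.4); qd <- runif(11, -1, 1); qdd <- runif(11, -3, 3)
    tau_ref <- lagrangian_tau(sk, q, qd, qdd)
    r <- skeleton_dynamics_residual(sk, q, qd, qdd)
    # oracle accuracy is limited by its finite differences (~1e-4 absolute)
    expect_lt(max(abs(r - tau_ref)), 5e-3)
  }
})

test_that("mass matrix is symmetric positive definite; degenerate inertia errors", {
  set.seed(3)
  M <- mass_matrix(test_skel, runif(11, -0.3, 0.3))
  expect_lt(max(abs(M - t(M))), 1e-9)
  expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  sk_bad <- test_skel
  sk_bad$segments$toe_r$mass <- -1
  expect_error(skeleton_dynamics_residual(sk_bad, rep(0, 11), rep(0, 11),
                                          rep(0, 11)), "masses")
})

test_that("torque-free contact-free motion conserves energy to 0.1% over 1 s", {
  sk <- test_skel
  q <- rep(0, 11); q[2] <- 2; q[4] <- 0.4; q[9] <- 0.6
  qd <- rep(0, 11); qd[4] <- 0.5; qd[8] <- -0.4
  e0 <- gaitfes:::mechanical_energy(sk, q, qd)
  h <- 2e-4
  deriv <- function(st) {
    qdd <- gaitfes:::forward_dynamics(sk, st[1:11], st[12:22])
    c(st[12:22], qdd)
  }
  st <- c(q, qd)
  for (k in seq_len(round(1 / h))) {   # RK4
    k1 <- deriv(st); k2 <- deriv(st + h / 2 * k1)
    k3 <- deriv(st + h / 2 * k2); k4 <- deriv(st + h * k3)
    st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  e1 <- gaitfes:::mechanical_energy(sk, st[1:11], st[12:22])
  # drift relative to the kinetic/potential scale of the motion
  expect_lt(abs(e1 - e0) / max(abs(e0), 100), 1e-3)
})
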