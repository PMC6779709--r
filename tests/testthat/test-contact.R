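test_that("contact element placement retains points inside the outline", {
  # full box, spacing = length/4: all 5 grid points kept
  es <- place_contact_elements(list(x_range = c(0, 0.2), mtp_x = 0.21), 0.05)
  expect_equal(nrow(es), 5)
  expect_true(all(es$segment == "hindfoot"))
  # front 30% excluded
  es2 <- place_contact_elements(list(x_range = c(0, 0.2), mtp_x = 0.21,
                                     keep = list(c(0, 0.14))), 0.05)
  expect_equal(nrow(es2), 3)
  # random outlines match a brute-force containment oracle
  set.seed(11)
  for (k in 1:10) {
    cuts <- sort(runif(2, 0, 0.2))
    keep <- list(c(0, cuts[1]), c(cuts[2], 0.2))
    es3 <- place_contact_elements(list(x_range = c(0, 0.2), mtp_x = 0.15,
                                       keep = keep), 0.02)
    xs <- seq(0, 0.2, by = 0.02)
    inside <- vapply(xs, function(x)
      any(vapply(keep, function(iv) x >= iv[1] & x <= iv[2], TRUE)), TRUE)
    expect_equal(nrow(es3), sum(inside))
  }
  expect_error(place_contact_elements(list(x_range = c(0, 0.2),
                                           keep = list(c(-1, -0.5))), 0.05),
               "zero contact elements")
  expect_error(place_contact_elements(list(x_range = c(0, 0.2)), -0.01),
               "spacing")
})

test_that("elements split between hindfoot and toes at the metatarsal joint", {
  es <- default_contact_elements(test_skel)
  expect_equal(sum(es$segment == "hindfoot"), 6)
  expect_equal(sum(es$segment == "toes"), 3)
})

test_that("element force law matches its formula and is never adhesive", {
  cp <- contact_params(stiffness = 1e9, exponent = 3, damping = 1,
                      mu_d = 0.8, mu_v = 0.5, v_smooth = 0.05,
                      belt_speed = 0.6, lin_stiffness = 3000)
  # above ground: only the smoothing floor remains
  f_air <- element_forces(0.01, 0, 0, cp)
  expect_lt(f_air$normal, 1e-2)
  # slipping exactly with the belt: no tangential force
  f_belt <- element_forces(-0.005, 0.6, 0, cp)
  expect_equal(f_belt$tangential, 0, tolerance = 1e-9)
  # formula oracle at 5 mm penetration, zero rate, zero slip speed rel belt
  d <- gaitfes:::smooth_pos(0.005, cp$depth_smooth)
  n_ref <- (1e9 * d^3 + 3000 * d) * gaitfes:::smooth_pos(1, 0.05)
  expect_equal(f_belt$normal, n_ref, tolerance = 1e-9)
  # strictly increasing in depth, never negative with strong unloading rate
  depths <- seq(-0.002, 0.01, length.out = 30)
  ns <- element_forces(-depths, 0, 0, cp)$normal
  expect_true(all(diff(ns) > 0))
  expect_true(all(element_forces(-0.005, 0, 5, cp)$normal >= 0))
})

test_that("ground reactions aggregate element forces with a defined CoP", {
  sk <- test_skel
  es <- default_contact_elements(sk)
  cp <- contact_params()
  # feet in the air
  q <- rep(0, 11); q[2] <- 1.2
  gr <- aggregate_ground_reactions(sk, q, rep(0, 11), es, cp)
  expect_false(gr$r$cop_defined)
  expect_lt(gr$r$fy, 1)
  # feet penetrating: resultant equals a brute-force summation oracle
  q[2] <- 0.97 - 0.004
  gr2 <- aggregate_ground_reactions(sk, q, rep(0, 11), es, cp)
  fk <- gaitfes:::fk_batched(sk, gaitfes:::as_coord_array(q),
                             gaitfes:::as_coord_array(rep(0, 11)), NULL)
  fy_ref <- 0; fx_ref <- 0; xw <- 0
  for (i in seq_len(nrow(es))) {
    e <- es[i, ]
    seg <- if (e$segment == "hindfoot") "foot_r" else "toe_r"
    py <- if (e$segment == "hindfoot") sk$foot_sole_y else 0
    pk <- gaitfes:::segment_point_kin(fk[[seg]], e$x, py)
    f <- element_forces(pk$y[1, 1], pk$vx[1, 1], pk$vy[1, 1], cp)
    fy_ref <- fy_ref + f$normal; fx_ref <- fx_ref + f$tangential
    xw <- xw + pk$x[1, 1] * f$normal
  }
  expect_equal(gr2$r$fy, fy_ref, tolerance = 1e-9)
  expect_equal(gr2$r$fx, fx_ref, tolerance = 1e-9)
  expect_true(gr2$r$cop_defined)
  expect_equal(gr2$r$cop, xw / fy_ref, tolerance = 1e-9)
})

test_that("ground reactions are differentiable in the state", {
  sk <- test_skel; es <- default_contact_elements(sk); cp <- contact_params()
  set.seed(5)
  q0 <- rep(0, 11); q0[2] <- 0.968; q0[4] <- 0.1; q0[5] <- 0.15
  qd0 <- runif(11, -0.2, 0.2)
  f0 <- aggregate_ground_reactions(sk, q0, qd0, es, cp)$r$fy
  for (i in c(2, 4, 6)) {
    h <- 1e-6
    qp <- q0; qp[i] <- qp[i] + h
    qm <- q0; qm[i] <- qm[i] - h
    g_c <- (aggregate_ground_reactions(sk, qp, qd0, es, cp)$r$fy -
              aggregate_ground_reactions(sk, qm, qd0, es, cp)$r$fy) / (2 * h)
    h2 <- 5e-7
    qp2 <- q0; qp2[i] <- qp2[i] + h2
    qm2 <- q0; qm2[i] <- qm2[i] - h2
    g_c2 <- (aggregate_ground_reactions(sk, qp2, qd0, es, cp)$r$fy -
               aggregate_ground_reactions(sk, qm2, qd0, es, cp)$r$fy) / (2 * h2)
    # two step sizes agree: no kinks at this (loaded) state
    expect_lt(abs(g_c - g_c2) / max(abs(g_c), 1), 1e-3)
  }
})
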