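test_that("harmonic differentiation matches closed forms on periodic signals", {
  t_end <- 1.2
  tt <- seq(0, t_end, length.out = 101)
  x <- sin(2 * pi * tt / t_end) + 0.3 * cos(4 * pi * tt / t_end)
  pd <- periodic_derivatives(tt, x, n_harm = 8)
  xd_ref <- 2 * pi / t_end * cos(2 * pi * tt / t_end) -
    0.3 * 4 * pi / t_end * sin(4 * pi * tt / t_end)
  expect_lt(max(abs(pd$xd - xd_ref)) / max(abs(xd_ref)), 0.01)
  xdd_ref <- -(2 * pi / t_end)^2 * sin(2 * pi * tt / t_end) -
    0.3 * (4 * pi / t_end)^2 * cos(4 * pi * tt / t_end)
  expect_lt(max(abs(pd$xdd - xdd_ref)) / max(abs(xdd_ref)), 0.01)
  # a linear trend (pelvis forward travel) passes through untouched
  x2 <- 0.6 * tt + 0.05 * sin(2 * pi * tt / t_end)
  pd2 <- periodic_derivatives(tt, x2, n_harm = 8)
  # mean over one period (the grid duplicates its endpoint)
  expect_equal(mean(pd2$xd[1:100]), 0.6, tolerance = 1e-6)
})

test_that("inverse dynamics round-trips known torques in a contact-free swing", {
  sk <- test_skel
  # forward-simulate a torque-driven motion hanging in space, then recover
  # the applied torques from the trajectory
  tau_fun <- function(t) {
    tau <- rep(0, 11)
    tau[4] <- 20 * sin(2 * pi * t)   # hip drive
    tau[5] <- -8 * cos(2 * pi * t)   # knee drive
    tau
  }
  h <- 5e-4
  n <- 400
  q <- matrix(0, n, 11); qd <- matrix(0, n, 11)
  q[1, 2] <- 2; q[1, 4] <- 0.3
  deriv <- function(st, t) {
    qdd <- gaitfes:::forward_dynamics(sk, st[1:11], st[12:22], tau_fun(t))
    c(st[12:22], qdd)
  }
  st <- c(q[1, ], qd[1, ])
  qdd_hist <- matrix(0, n, 11)
  for (k in 1:(n - 1)) {
    t_k <- (k - 1) * h
    k1 <- deriv(st, t_k); k2 <- deriv(st + h / 2 * k1, t_k + h / 2)
    k3 <- deriv(st + h / 2 * k2, t_k + h / 2); k4 <- deriv(st + h * k3, t_k + h)
    qdd_hist[k, ] <- k1[12:22]
    st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    q[k + 1, ] <- st[1:11]; qd[k + 1, ] <- st[12:22]
  }
  qdd_hist[n, ] <- deriv(st, (n - 1) * h)[12:22]
  grf0 <- list(r = list(fx = rep(0, n), fy = rep(0, n), cop = rep(NA_real_, n)),
               l = list(fx = rep(0, n), fy = rep(0, n), cop = rep(NA_real_, n)))
  id <- inverse_dynamics(q, qd, qdd_hist, grf0, sk)
  ts <- (seq_len(n) - 1) * h
  expect_lt(max(abs(id[, 4] - 20 * sin(2 * pi * ts))), 1e-6)
  expect_lt(max(abs(id[, 5] + 8 * cos(2 * pi * ts))), 1e-6)
  # unactuated coordinates carry no residual force
  expect_lt(max(abs(id[, c(1, 2, 3)])), 1e-6)
})

test_that("calibration inputs are validated", {
  # too few markers per segment
  md <- gaitfes:::expand_marker_defs(list(
    pelvis = list(PEL1 = c(0, 0.1), PEL2 = c(0.1, 0)),
    thigh = list(THI1 = c(0, -0.2)),
    shank = list(SHA1 = c(0, -0.2), SHA2 = c(0.02, -0.3)),
    foot = list(ANK = c(0, 0), HEE = c(-0.05, -0.06)),
    toe = list(TOE = c(0.05, 0), TO2 = c(0.02, 0.01))))
  fake_trial <- structure(list(t = 1:3), class = "gait_trial")
  expect_error(calibrate_joint_model(list(fake_trial), test_skel, md),
               "at least 2 markers")
  expect_error(calibrate_joint_model(list(), test_skel, md), "at least one")
  # IK with too few visible markers
  trial2 <- structure(list(t = c(0, 0.1),
                           markers = list(PEL1 = cbind(0:1, 1:2))),
                      class = "gait_trial")
  expect_error(inverse_kinematics(trial2, test_skel,
                                  md["PEL1"]), "3 visible markers")
  # missing ground-reaction channel blocks contact calibration
  trial3 <- structure(list(t = seq(0, 1.2, length.out = 5),
                           grf = list(r = list(fx = 1:5), l = list(fx = 1:5, fy = 1:5))),
                      class = "gait_trial")
  expect_error(calibrate_contact(trial3, NULL, NULL, test_model),
               "missing ground-reaction")
})

test_that("the full personalization recovers the perturbed quantities", {
  res <- pipeline_results()
  pat <- res$pat; pm <- res$pm
  # stage 1: joint centres back within 1 mm of truth on noiseless markers
  for (sg in c("thigh_r", "shank_r", "foot_r", "thigh_l", "shank_l", "foot_l")) {
    err <- pm$model$skel$segments[[sg]]$joint_in_parent -
      pat$model$skel$segments[[sg]]$joint_in_parent
    expect_lt(max(abs(err)), 1e-3)
  }
  expect_lt(pm$report$marker_rmse, 1e-4)
  # stage 2: EMG scales recovered along with fiber/tendon lengths
  scale_err <- vapply(names(pat$model$muscles$params), function(nm)
    abs(pm$model$muscles$params[[nm]]$emg_scale /
          pat$model$muscles$params[[nm]]$emg_scale - 1), 0)
  meas <- names(which(pat$model$emg_status == "measured"))
  expect_lt(stats::median(scale_err[meas]), 0.20)
  # stage 3: stiffness recovered decisively (the Coulomb/viscous friction
  # pair is degenerate at stance-phase slip speeds and is not asserted)
  expect_lt(abs(pm$model$contact$stiffness / pat$model$contact$stiffness - 1),
            0.10)
  # the verification problem's formulation is prediction, not tracking
  expect_false(any(grepl("track", pm$verification$cost_terms)))
})
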