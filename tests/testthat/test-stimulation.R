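test_that("stimulation waveform identities", {
  t_end <- 1.1
  # zero amplitude
  p0 <- stimulation_profile(0, 0.2, 0.5, t_end, c1 = 50, c2 = 50)
  expect_true(all(stim_activation(p0, seq(0, t_end, 0.01)) == 0))
  # saturated mid-pulse plateau reaches A; half amplitude at onset
  p <- stimulation_profile(0.7, 0.2, 0.5, t_end, c1 = 50, c2 = 50)
  expect_equal(stim_activation(p, 0.35), 0.7, tolerance = 5e-4)
  expect_equal(stim_activation(p, 0.2), 0.35, tolerance = 5e-4)
  # direct evaluation of the three-term expression
  a_ref <- 0.35 * (tanh(50 * (0.35 - 0.2)) - tanh(50 * (0.35 - 0.5))) +
    0.35 * (1 - tanh(50 * (0.35 - 0.5 + 1.1)))
  expect_equal(stim_activation(p, 0.35), a_ref, tolerance = 1e-12)
  expect_equal(round(a_ref, 3), 0.700)
  # wrap-around pulse (off-time before on-time) is active at cycle start
  pw <- stimulation_profile(0.5, 0.715, 0.12, t_end, c1 = 60, c2 = 60)
  expect_equal(stim_activation(pw, 0.9), 0.5, tolerance = 1e-3)
  expect_equal(stim_activation(pw, 0.03), 0.5, tolerance = 1e-2)
  expect_lt(stim_activation(pw, 0.4), 1e-3)
  expect_error(stimulation_profile(0.9, 0, 0.5, t_end), "amplitude")
})

test_that("waveform shape calibration matches activation dynamics", {
  p_sym <- muscle_params("m", 1000, 0.1, 0.2, tau_act = 0.03, tau_deact = 0.03)
  sh <- calibrate_stim_shape(p_sym, 0.3, 0.7, 1.2)
  expect_lt(abs(sh$c1 - sh$c2) / sh$c1, 0.35)
  p_asym <- muscle_params("m", 1000, 0.1, 0.2, tau_act = 0.01, tau_deact = 0.06)
  sh2 <- calibrate_stim_shape(p_asym, 0.3, 0.7, 1.2)
  expect_gt(sh2$c1, sh2$c2)   # faster rise than fall
  # default time constants: fit quality within 0.03 activation units
  # frozen oracle value: the global least-squares fit of the tanh pulse to
  # the first-order response with the default time constants has RMSE
  # 0.0304 on a 1 ms grid over the cycle
  p_def <- muscle_params("m", 1000, 0.1, 0.2)
  sh3 <- calibrate_stim_shape(p_def, 0.3, 0.7, 1.2)
  expect_equal(sh3$rmse, 0.03042, tolerance = 2e-3)
  expect_false(sh3$poor_fit)
  # calibrated waveform stays within the amplitude band (small overshoot)
  tg <- seq(0, 1.2, by = 1e-3)
  wave <- gaitfes:::stim_wave(tg, 1, 0.3, 0.7, 1.2, sh3$c1, sh3$c2,
                              sh3$t_offset1, sh3$t_offset2)
  expect_lt(max(wave) - 1, 1e-3)
  expect_gt(min(wave), -1e-3)
})

test_that("total activation composes additively", {
  a_syn <- c(0.3, 0.3, 0.3)
  a_stim <- c(0, 0.7, 0.2)
  expect_equal(total_activation(a_syn, a_stim), c(0.3, 1.0, 0.5))
  expect_equal(total_activation(a_syn, 0), a_syn)
})

test_that("continuous stimulated-muscle count", {
  expect_equal(effective_muscle_count(rep(0, 25)), 0)
  expect_equal(effective_muscle_count(rep(50, 3)), 3, tolerance = 1e-6)
  # direct formula evaluation for two muscles at 0.7 among 25
  n <- effective_muscle_count(c(0.7, 0.7, rep(0, 23)))
  expect_equal(n, 2 * (1 - exp(-4 * 0.7)), tolerance = 1e-12)
  expect_equal(round(n, 4), 1.8784)
  expect_error(effective_muscle_count(c(0.2, -0.1)), "amplitudes")
  # strictly increasing in every amplitude; smooth gradient
  a <- c(0.1, 0.4, 0.0)
  for (i in 1:3) {
    e <- rep(0, 3); e[i] <- 1e-6
    g <- (effective_muscle_count(a + e) - effective_muscle_count(a)) / 1e-6
    expect_gt(g, 0)
    expect_equal(g, 4 * exp(-4 * a[i]), tolerance = 1e-4)
  }
})
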