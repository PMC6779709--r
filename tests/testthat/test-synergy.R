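test_that("EMG processing chain recovers a known modulation envelope", {
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)
  expect_equal(max(abs(process_emg(rep(0, length(t)), rate))), 0)
  # pure DC vanishes after high-pass + demean
  expect_lt(max(process_emg(rep(3, length(t)), rate)), 1e-6)
  # amplitude-modulated 80 Hz carrier with a known 2 Hz modulator
  mod <- 0.6 + 0.4 * sin(2 * pi * 2 * t)
  raw <- mod * sin(2 * pi * 80 * t)
  env <- process_emg(raw, rate)
  trim <- 200:(length(t) - 200)   # ignore filter edge effects
  expect_gt(cor(env[trim], mod[trim]), 0.98)
  expect_error(process_emg(raw, rate, lp_cutoff = 600), "Nyquist")
})

test_that("NMF recovers exact and noisy low-rank structure", {
  set.seed(21)
  W0 <- matrix(runif(8 * 2), 8, 2); C0 <- matrix(runif(2 * 60), 2, 60)
  X <- W0 %*% C0
  s <- extract_synergies(X, 2, replicates = 5, seed = 4)
  expect_gte(s$vaf_total, 99.9)
  expect_true(all(s$W >= 0) && all(s$C >= 0))
  expect_equal(unname(sqrt(colSums(s$W^2))), c(1, 1), tolerance = 1e-9)
  # rank-3 + 5% noise: matched columns of W recovered (cosine > 0.9)
  W3 <- matrix(runif(10 * 3), 10, 3); C3 <- matrix(runif(3 * 80), 3, 80)
  Xn <- W3 %*% C3 * (1 + matrix(rnorm(10 * 80, 0, 0.05), 10, 80))
  Xn[Xn < 0] <- 0
  s3 <- extract_synergies(Xn, 3, replicates = 20, seed = 9)
  Wn <- sweep(W3, 2, sqrt(colSums(W3^2)), "/")
  sim <- abs(crossprod(Wn, s3$W))
  # greedy column matching
  best <- apply(sim, 1, max)
  expect_true(all(best > 0.9))
  expect_error(extract_synergies(-X, 2), "non-negative")
})

test_that("NMF objective is non-increasing across multiplicative updates", {
  set.seed(2)
  X <- matrix(runif(6 * 40), 6, 40)
  W0 <- matrix(runif(6 * 2, 0.1, 1), 6, 2)
  C0 <- matrix(runif(2 * 40, 0.1, 1), 2, 40)
  fit <- gaitfes:::nmf_multiplicative(X, 2, W0, C0, max_iter = 300, rel_tol = 0,
                                      trace = TRUE)
  expect_true(all(diff(fit$sse_trace) <= 1e-10))
})

test_that("synergy-count selection follows the per-muscle VAF rule", {
  # two clearly distinct temporal patterns driving separate muscle groups
  s_t <- seq(0, 1, length.out = 50)
  C0 <- rbind(exp(-((s_t - 0.25) / 0.12)^2), exp(-((s_t - 0.7) / 0.12)^2))
  W0 <- rbind(c(1, 0), c(0.9, 0.1), c(0.8, 0), c(0, 1), c(0.1, 0.9), c(0, 0.8))
  X <- W0 %*% C0
  ch <- choose_num_synergies(X, replicates = 4)
  expect_equal(ch$n_syn, 2)
  expect_equal(ch$n_syn_total, 2)
  # VAF is non-decreasing with rank
  expect_true(all(diff(ch$vaf_by_rank$vaf_total) > -0.5))
  # one muscle orthogonal to a rank-2 bulk: per-muscle rule needs 3,
  # total-VAF rule is satisfied at 2 (the bulk dominates the variance)
  odd <- matrix(exp(-((s_t - 0.5) / 0.05)^2) * 0.25, 1)
  X2 <- rbind(8 * X, odd)
  ch2 <- choose_num_synergies(X2, replicates = 6)
  expect_equal(ch2$n_syn_total, 2)
  expect_gt(ch2$n_syn, 2)
  expect_error(choose_num_synergies(X, per_muscle_threshold = 101), "threshold")
})

test_that("missing-channel reconstruction is a clamped linear map", {
  set.seed(8)
  C <- matrix(runif(3 * 40), 3, 40)
  expect_true(all(reconstruct_missing(C, c(0, 0, 0)) == 0))
  expect_equal(reconstruct_missing(C, c(0, 1, 0)), pmin(C[2, ], 1))
  # weights of a synthesized "missing" muscle recovered by least squares
  w_true <- c(0.4, 0.2, 0.3)
  a <- as.numeric(w_true %*% C)
  w_hat <- coef(lm(a ~ t(C) - 1))
  expect_lt(max(abs(w_hat - w_true)), 1e-6)
  expect_equal(reconstruct_missing(C, w_hat), a, tolerance = 1e-6)
  expect_error(reconstruct_missing(C, c(0.1, 0.2)), "n_syn")
  expect_error(reconstruct_missing(C, c(-0.1, 0, 0)), "non-negative")
})

test_that("copied channels receive their donor envelope exactly", {
  emg <- cbind(semiten = c(0.1, 0.5, 0.3))
  status <- c(semiten = "measured", semimem = "copied")
  out <- apply_copied_channels(emg, status, c(semimem = "semiten"))
  expect_identical(unname(out[, "semimem"]), unname(emg[, "semiten"]))
  expect_error(apply_copied_channels(emg, status, c()), "donor")
})
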