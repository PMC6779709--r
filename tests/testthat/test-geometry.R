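test_that("locally linear geometry is fitted essentially exactly", {
  # over a narrow angular window any straight-line path is linear in the
  # angle, so a low-degree surrogate must reproduce length and (constant)
  # moment arm at oracle accuracy
  sk <- test_skel; mus <- test_muscles
  rng <- list(ankle = c(-0.02, 0.02))
  geom <- fit_surrogate_geometry(sk, mus$paths$soleus_r, rng, degree = 3)
  q <- rep(0, 11); q[6] <- 0.01
  mk <- muscle_tendon_kinematics(q, rep(0, 11), geom)
  expect_lt(abs(mk$lmt - path_length(sk, mus$paths$soleus_r, q)), 1e-8)
  oracle <- path_moment_arms(sk, mus$paths$soleus_r, q)
  expect_lt(abs(mk$arms[["ankle_r"]] - oracle[["ankle_r"]]), 1e-6)
})

test_that("surrogate moment arms equal the negative length gradient of the path model", {
  sk <- test_skel; mus <- test_muscles
  for (nm in c("iliopsoas_r", "gastrocnemius_r", "hamstrings_l")) {
    geom <- test_surrogates[[nm]]
    set.seed(42)
    for (k in 1:5) {
      q <- rep(0, 11)
      for (j in seq_along(geom$spans)) {
        rg <- geom$ranges[[j]]
        q[geom$coord_idx[j]] <- runif(1, rg[1] + 0.05, rg[2] - 0.05)
      }
      mk <- muscle_tendon_kinematics(q, rep(0, 11), geom)
      # independent finite-difference oracle on the geometric path model
      oracle <- path_moment_arms(sk, mus$paths[[nm]], q)
      expect_lt(max(abs(mk$arms - oracle)), 1e-3)
      expect_lt(abs(mk$lmt - path_length(sk, mus$paths[[nm]], q)), 5e-4)
    }
    # internal consistency: the surrogate's stored max arm residual against
    # its own length gradient is zero by construction; check numerically
    q <- vapply(geom$ranges, mean, 0)
    qfull <- rep(0, 11); qfull[geom$coord_idx] <- q
    mk <- muscle_tendon_kinematics(qfull, rep(0, 11), geom)
    h <- 1e-6
    for (j in seq_along(geom$spans)) {
      qp <- qfull; qp[geom$coord_idx[j]] <- qp[geom$coord_idx[j]] + h
      qm <- qfull; qm[geom$coord_idx[j]] <- qm[geom$coord_idx[j]] - h
      dl <- (muscle_tendon_kinematics(qp, rep(0, 11), geom)$lmt -
               muscle_tendon_kinematics(qm, rep(0, 11), geom)$lmt) / (2 * h)
      expect_lt(abs(mk$arms[j] + dl), 1e-4)
    }
  }
})

test_that("muscle-tendon velocity follows the chain rule", {
  geom <- test_surrogates$soleus_r
  q <- rep(0, 11); q[6] <- -0.1
  qd <- rep(0, 11)
  expect_equal(muscle_tendon_kinematics(q, qd, geom)$vmt, 0)
  qd[6] <- 1
  mk <- muscle_tendon_kinematics(q, qd, geom)
  expect_equal(mk$vmt, -mk$arms[["ankle_r"]], tolerance = 1e-12)
})

test_that("degenerate fits and out-of-range queries error clearly", {
  sk <- test_skel; mus <- test_muscles
  expect_error(fit_surrogate_geometry(sk, mus$paths$soleus_r,
                                      default_joint_ranges(), degree = 0),
               "degree")
  geom <- test_surrogates$soleus_r
  q <- rep(0, 11); q[6] <- 2
  expect_error(muscle_tendon_kinematics(q, rep(0, 11), geom), "ankle_r")
})
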