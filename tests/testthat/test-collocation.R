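min_jerk_nlp <- function(N = 20) {
  ocp <- ocp_definition(n_q = 1, N = N, t_end = 1, scale_q = 1, scale_qd = 2,
                        scale_qdd = 10, scale_jerk = 100)
  ocp <- add_cost(ocp, "jerk", 1e-4, function(tr) sqrt(tr$qw) * tr$jerk[[1]])
  ocp <- add_terminal_constraint(ocp, "end", function(tr) {
    np <- tr$np
    rbind(tr$q[[1]][np, , drop = FALSE] - 1, tr$qd[[1]][np, , drop = FALSE],
          tr$qdd[[1]][np, , drop = FALSE])
  })
  ocp <- set_bounds(ocp, "x0", c(0, 0, 0), c(0, 0, 0))
  transcribe(ocp)
}

test_that("rest-to-rest transcription reproduces the minimum-jerk quintic", {
  nlp <- min_jerk_nlp()
  sol <- solve_ocp(nlp)
  expect_equal(sol$status, "converged")
  expect_lte(sol$max_violation, 1e-6)
  tt <- sol$traj$t
  q_exact <- 10 * tt^3 - 15 * tt^4 + 6 * tt^5
  expect_lt(max(abs(sol$traj$q[[1]][, 1] - q_exact)), 1e-4)
})

test_that("solves are deterministic and cost terms sum to the objective", {
  nlp <- min_jerk_nlp(10)
  s1 <- solve_ocp(nlp)
  s2 <- solve_ocp(nlp)
  expect_identical(s1$z, s2$z)
  terms <- evaluate_cost_terms(s1)
  expect_equal(sum(unlist(terms)), s1$objective, tolerance = 1e-12)
})

test_that("transcription bookkeeping and input validation", {
  expect_error(ocp_definition(n_q = 1, N = 0, t_end = 1), "mesh")
  ocp <- ocp_definition(n_q = 2, n_u = 1, N = 8, t_end = 1)
  expect_error(set_bounds(ocp, "u", 1, -1), "inconsistent")
  ocp <- add_path_constraint(ocp, "c1", function(tr) tr$q[[1]][tr$node_idx, , drop = FALSE])
  nlp <- transcribe(ocp)
  # variables: (N+4) free chain coordinates per jerk-driven coordinate plus
  # one control value per node
  expect_equal(nlp$info$n_var, 2 * (8 + 4) + 9)
  expect_equal(nlp$info$n_collocation_points, 17)
  expect_equal(nlp$info$n_defects_eliminated, 3 * 2 * 8)
  expect_equal(nlp$info$n_path_rows_nominal, 9)
})

test_that("pendulum swing-up objective is mesh-converged and feasible to 1e-6", {
  mk <- function(N) {
    m <- 1; l <- 1; g <- 9.81
    ocp <- ocp_definition(n_q = 1, n_u = 1, N = N, t_end = 2, scale_q = 3,
                          scale_qd = 6, scale_qdd = 20, scale_jerk = 200,
                          scale_u = 20)
    ocp <- add_cost(ocp, "effort", 1e-2, function(tr) sqrt(tr$qw) * tr$u[[1]])
    ocp <- add_path_constraint(ocp, "dynamics", function(tr) {
      ni <- tr$node_idx
      (m * l^2 * tr$qdd[[1]] + m * g * l * sin(tr$q[[1]]) - tr$u[[1]])[ni, , drop = FALSE]
    }, scale = 10)
    ocp <- add_terminal_constraint(ocp, "end", function(tr) {
      np <- tr$np
      rbind(tr$q[[1]][np, , drop = FALSE] - pi, tr$qd[[1]][np, , drop = FALSE],
            tr$qdd[[1]][np, , drop = FALSE])
    })
    ocp <- set_bounds(ocp, "x0", c(0, 0, -50), c(0, 0, 50))
    transcribe(ocp)
  }
  s1 <- solve_ocp(mk(20))
  s2 <- solve_ocp(mk(40))
  expect_equal(s1$status, "converged")
  expect_equal(s2$status, "converged")
  expect_lte(s1$max_violation, 1e-6)
  expect_lt(abs(s1$objective - s2$objective) / s2$objective, 0.01)
})

test_that("periodicity residuals report start-to-end mismatches", {
  ocp <- ocp_definition(n_q = 1, N = 10, t_end = 1)
  ocp <- add_cost(ocp, "jerk", 1e-6, function(tr) sqrt(tr$qw) * tr$jerk[[1]])
  ocp <- add_periodicity(ocp, "q", function(tr) tr$q[[1]])
  nlp <- transcribe(ocp)
  # constant trajectory: zero residual
  z0 <- nlp$make_guess(matrix(0.3, nlp$mesh$np, 1))
  sol <- list(traj = nlp$unpack(matrix(z0, ncol = 1)), nlp = nlp)
  class(sol) <- "ocp_solution"
  expect_lt(abs(periodicity_residuals(sol)[["q"]]), 1e-9)
  # full-period sinusoid: zero; 0.9-period sinusoid: analytic difference
  tt <- nlp$mesh$t
  for (per in c(1, 0.9)) {
    zs <- nlp$make_guess(matrix(sin(2 * pi * tt / per), ncol = 1))
    sols <- list(traj = nlp$unpack(matrix(zs, ncol = 1)), nlp = nlp)
    class(sols) <- "ocp_solution"
    ref <- sin(2 * pi * 1 / per) - 0
    expect_equal(periodicity_residuals(sols)[["q"]], ref, tolerance = 1e-3)
  }
  expect_error(periodicity_residuals(sol, "nope"), "unknown")
})

test_that("interpolated velocity is the derivative of interpolated position", {
  nlp <- min_jerk_nlp(12)
  sol <- solve_ocp(nlp)
  tr <- sol$traj
  # central differences of q across collocation points vs qd at midpoints
  h <- tr$t[2] - tr$t[1]
  mid <- seq(2, tr$np - 1, by = 2)
  qd_fd <- (tr$q[[1]][mid + 1, 1] - tr$q[[1]][mid - 1, 1]) / (2 * h)
  # agreement to the O(h^2 q''') truncation of the finite difference
  h_err <- h^2 / 6 * max(abs(tr$jerk[[1]][, 1]))
  expect_lt(max(abs(qd_fd - tr$qd[[1]][mid, 1])), 2 * h_err + 1e-9)
})
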