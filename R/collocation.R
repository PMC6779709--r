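# Direct-collocation optimal control engine.
#
# Problem structure shared by every personalization/treatment problem:
#  - jerk-driven coordinate chains: states (q, qd, qdd) per coordinate with
#    joint jerk as the control, so skeletal dynamics can be imposed in an
#    inverse sense as path constraints;
#  - optional algebraic controls (synergy activations, auxiliary inputs);
#  - optional static parameters (contact properties, synergy vectors,
#    stimulation amplitude/timing).
#
# Transcription: a fixed mesh of N intervals over one cycle with collocation
# at the N+1 nodes and N interval midpoints (Hermite-Simpson point layout).
# Because the state chain q -> qd -> qdd -> jerk is linear and the jerk
# control is piecewise linear, the collocation defects are eliminated in
# closed form: states at every collocation point are an exact linear map of
# (initial state, jerk at nodes), and Simpson quadrature is exact for the
# eliminated subsystem. What remains is a dense nonlinear least-squares /
# constrained problem in (initial states, jerks, controls, statics), solved
# by an augmented-Lagrangian Levenberg-Marquardt method with batched
# finite-difference Jacobians (see solver.R).

#' Define a jerk-chain optimal control problem
#'
#' @param n_q number of jerk-driven coordinates.
#' @param n_u number of algebraic controls (piecewise linear on the mesh).
#' @param n_s number of static parameters.
#' @param N mesh intervals (>= 1) over one cycle.
#' @param t_end cycle duration (s).
#' @param scale_q,scale_qd,scale_qdd,scale_jerk,scale_u characteristic
#'   magnitudes used to scale variables to O(1).
#' @param scale_s static-parameter scales (recycled to `n_s`).
#' @return `ocp_definition` object; populate with [add_cost()],
#'   [add_path_constraint()], [add_terminal_constraint()],
#'   [add_periodicity()] and bound setters before [transcribe()].
#' @export
ocp_definition <- function(n_q, n_u = 0, n_s = 0, N, t_end,
                           scale_q = 1, scale_qd = 5, scale_qdd = 50,
                           scale_jerk = 1000, scale_u = 1, scale_s = 1) {
  if (N < 1) stop_gaitfes("mesh must have at least one interval")
  if (t_end <= 0) stop_gaitfes("t_end must be > 0")
  structure(list(
    n_q = n_q, n_u = n_u, n_s = n_s, N = as.integer(N), t_end = t_end,
    scale_q = rep_len(scale_q, n_q), scale_qd = rep_len(scale_qd, n_q),
    scale_qdd = rep_len(scale_qdd, n_q), scale_jerk = rep_len(scale_jerk, n_q),
    scale_u = rep_len(scale_u, max(n_u, 1))[seq_len(n_u)],
    scale_s = rep_len(scale_s, max(n_s, 1))[seq_len(n_s)],
    cost_terms = list(), path_constraints = list(),
    terminal_constraints = list(), periodicity = list(),
    bounds = list(), fixed = list()
  ), class = "ocp_definition")
}

#' Add a weighted least-squares cost term
#'
#' `fn(traj)` must return a residual matrix (rows x n_case); the term's value
#' is `weight * sum(residual^2)` per case. Integral terms should multiply
#' rows by `sqrt` of the quadrature weights `traj$qw`.
#' @param ocp an `ocp_definition`. @param name term name. @param weight >= 0.
#' @param fn batched residual function of a trajectory.
#' @export
add_cost <- function(ocp, name, weight, fn) {
  if (weight < 0) stop_gaitfes("cost weights must be >= 0")
  ocp$cost_terms[[name]] <- list(weight = weight, fn = fn)
  ocp
}

#' Add a path (or general) constraint
#'
#' @param ocp an `ocp_definition`. @param name constraint name.
#' @param fn batched function of a trajectory returning (rows x n_case);
#'   equality constraints are driven to 0, inequalities to `<= 0`.
#' @param scale characteristic magnitude; violations are reported on the
#'   scaled quantity.
#' @param type `"eq"` or `"ineq"`.
#' @export
add_path_constraint <- function(ocp, name, fn, scale = 1, type = c("eq", "ineq")) {
  type <- match.arg(type)
  ocp$path_constraints[[name]] <- list(fn = fn, scale = scale, type = type)
  ocp
}

#' Add a terminal (boundary) constraint
#' @inheritParams add_path_constraint
#' @export
add_terminal_constraint <- function(ocp, name, fn, scale = 1, type = c("eq", "ineq")) {
  type <- match.arg(type)
  ocp$terminal_constraints[[name]] <- list(fn = fn, scale = scale, type = type)
  ocp
}

#' Add a periodicity pair
#'
#' Enforces `value(t_end) - value(0) = shift` for the quantity computed by
#' `fn(traj)` (an np x n_case matrix).
#' @param ocp an `ocp_definition`. @param name pair name.
#' @param fn batched trajectory quantity. @param shift offset (e.g. stride
#'   length for pelvis forward translation on a treadmill). @param scale
#'   characteristic magnitude.
#' @export
add_periodicity <- function(ocp, name, fn, shift = 0, scale = 1) {
  ocp$periodicity[[name]] <- list(fn = fn, shift = shift, scale = scale)
  ocp
}

#' Set bounds on a variable group
#' @param ocp an `ocp_definition`.
#' @param group one of `"x0"`, `"jerk"`, `"u"`, `"s"`.
#' @param lower,upper bound vectors (recycled to the group's width; `x0` is
#'   ordered q then qd then qdd).
#' @export
set_bounds <- function(ocp, group, lower, upper) {
  if (any(lower > upper))
    stop_gaitfes("inconsistent bounds (lower > upper) for group '", group, "'")
  ocp$bounds[[group]] <- list(lower = lower, upper = upper)
  ocp
}

# Transcription matrices for one jerk-driven coordinate.
#
# Node-state representation: z = (q at N+1 nodes, qd, qdd, jerk at nodes),
# linked by 3N linear "defect" relations (exact integration of the chain with
# piecewise-linear jerk). The defects are eliminated through an orthonormal
# basis Qn of their null space computed on *scaled* variables, so the free
# coordinates y (length N+4) are well-conditioned: states at all collocation
# points are `T_y %*% y` with O(1) singular values. (A raw (x0, jerk)
# parametrization is equivalent but catastrophically ill-conditioned for
# Gauss-Newton solvers: jerk columns accumulate ~t^3.)
chain_matrices <- function(N, t_end, sq = 1, sqd = 1, sqdd = 1, sj = 1) {
  h <- t_end / N
  n_nodes <- N + 1
  nz <- 4 * n_nodes
  np <- 2 * N + 1
  e <- function(group, k) {          # unit row in z-space; k is 0-based node
    v <- rep(0, nz); v[group * n_nodes + k + 1] <- 1; v
  }
  adv <- function(k, tau) {          # state rows at local time tau in interval k
    q <- e(0, k); qd <- e(1, k); qdd <- e(2, k)
    j0 <- e(3, k); j1 <- e(3, k + 1)
    dj <- (j1 - j0) / h
    list(q = q + tau * qd + tau^2 / 2 * qdd + tau^3 / 6 * j0 + tau^4 / 24 * dj,
         qd = qd + tau * qdd + tau^2 / 2 * j0 + tau^3 / 6 * dj,
         qdd = qdd + tau * j0 + tau^2 / 2 * dj,
         j = j0 + tau * dj)
  }
  D <- matrix(0, 3 * N, nz)
  for (k in 0:(N - 1)) {
    a <- adv(k, h)
    D[3 * k + 1, ] <- a$q - e(0, k + 1)
    D[3 * k + 2, ] <- a$qd - e(1, k + 1)
    D[3 * k + 3, ] <- a$qdd - e(2, k + 1)
  }
  Tq <- matrix(0, np, nz); Tqd <- Tq; Tqdd <- Tq; Tj <- Tq
  for (k in 0:(N - 1)) {
    Tq[2 * k + 1, ] <- e(0, k); Tqd[2 * k + 1, ] <- e(1, k)
    Tqdd[2 * k + 1, ] <- e(2, k); Tj[2 * k + 1, ] <- e(3, k)
    m <- adv(k, h / 2)
    Tq[2 * k + 2, ] <- m$q; Tqd[2 * k + 2, ] <- m$qd
    Tqdd[2 * k + 2, ] <- m$qdd; Tj[2 * k + 2, ] <- m$j
  }
  Tq[np, ] <- e(0, N); Tqd[np, ] <- e(1, N)
  Tqdd[np, ] <- e(2, N); Tj[np, ] <- e(3, N)
  # scale z, then orthonormal null-space basis of the scaled defects
  sigma <- c(rep(sq, n_nodes), rep(sqd, n_nodes), rep(sqdd, n_nodes),
             rep(sj, n_nodes))
  Ds <- D * rep(sigma, each = nrow(D))
  qrt <- qr(t(Ds))
  Qfull <- qr.Q(qrt, complete = TRUE)
  Qn <- Qfull[, (3 * N + 1):nz, drop = FALSE]      # nz x (N+4), orthonormal
  map <- function(Tz) (Tz * rep(sigma, each = np)) %*% Qn
  t_col <- seq(0, t_end, length.out = np)
  qw <- rep(0, np)
  for (k in 0:(N - 1)) {
    i <- 2 * k + 1
    qw[i] <- qw[i] + h / 6; qw[i + 1] <- qw[i + 1] + 4 * h / 6
    qw[i + 2] <- qw[i + 2] + h / 6
  }
  list(Tq = map(Tq), Tqd = map(Tqd), Tqdd = map(Tqdd), Tj = map(Tj),
       Qn = Qn, sigma = sigma, n_nodes = n_nodes, t = t_col, qw = qw, h = h,
       np = np, ny = N + 4)
}

#' Transcribe an optimal control problem to a nonlinear program
#'
#' @param ocp an `ocp_definition`.
#' @return `ocp_nlp`: variable layout, scaled start/bounds, the batched
#'   residual-block function consumed by the solver, an `unpack` closure
#'   mapping a variable vector to a trajectory, and bookkeeping info
#'   (variable and constraint counts, Jacobian sparsity summary).
#' @export
transcribe <- function(ocp) {
  n_nodes <- ocp$N + 1
  cms <- lapply(seq_len(ocp$n_q), function(i)
    chain_matrices(ocp$N, ocp$t_end, sq = ocp$scale_q[i], sqd = ocp$scale_qd[i],
                   sqdd = ocp$scale_qdd[i], sj = ocp$scale_jerk[i]))
  cm <- cms[[1]]
  ny <- cm$ny
  n_y <- ny * ocp$n_q
  n_u_tot <- n_nodes * ocp$n_u
  nz <- n_y + n_u_tot + ocp$n_s
  idx <- list(
    y = lapply(seq_len(ocp$n_q), function(i) (i - 1) * ny + seq_len(ny)),
    u = n_y + seq_len(n_u_tot),
    s = n_y + n_u_tot + seq_len(ocp$n_s))
  z_scale <- c(rep(1, n_y), rep(ocp$scale_u, each = n_nodes), ocp$scale_s)
  # linear interpolation of node controls onto collocation points
  Uint <- matrix(0, cm$np, n_nodes)
  for (k in 0:(ocp$N - 1)) {
    Uint[2 * k + 1, k + 1] <- 1
    Uint[2 * k + 2, k + 1] <- 0.5; Uint[2 * k + 2, k + 2] <- 0.5
  }
  Uint[cm$np, n_nodes] <- 1
  unpack <- function(Z) {       # Z: optimization variables (physical u/s), nz x m
    m <- ncol(Z)
    # per-coordinate matrices (np x m) — lists avoid accidental dim dropping
    q <- qd <- qdd <- jerk <- vector("list", ocp$n_q)
    for (i in seq_len(ocp$n_q)) {
      Y <- Z[idx$y[[i]], , drop = FALSE]
      q[[i]] <- cms[[i]]$Tq %*% Y; qd[[i]] <- cms[[i]]$Tqd %*% Y
      qdd[[i]] <- cms[[i]]$Tqdd %*% Y; jerk[[i]] <- cms[[i]]$Tj %*% Y
    }
    u <- vector("list", ocp$n_u)
    for (j in seq_len(ocp$n_u)) {
      Un <- Z[idx$u[(j - 1) * n_nodes + seq_len(n_nodes)], , drop = FALSE]
      u[[j]] <- Uint %*% Un
    }
    s <- Z[idx$s, , drop = FALSE]
    list(t = cm$t, qw = cm$qw, np = cm$np, m = m, q = q, qd = qd, qdd = qdd,
         jerk = jerk, u = u, s = s, t_end = ocp$t_end,
         # path constraints are imposed at mesh nodes (odd rows); the
         # midpoints serve Simpson quadrature and reporting
         node_idx = seq(1, cm$np, by = 2),
         # scratch environment letting cost/constraint closures share one
         # evaluation of an expensive model pipeline per batch
         cache = new.env(parent = emptyenv()))
  }
  # least-squares fit of the chain coordinates to a sampled trajectory
  make_guess <- function(q_target, u_target = NULL, s0 = NULL) {
    z <- numeric(nz)
    for (i in seq_len(ocp$n_q)) {
      A <- rbind(cms[[i]]$Tq, 1e-6 * cms[[i]]$Tj)
      b <- c(q_target[, i], rep(0, cm$np))
      z[idx$y[[i]]] <- qr.coef(qr(A), b)
    }
    if (!is.null(u_target)) {
      for (j in seq_len(ocp$n_u)) {
        z[idx$u[(j - 1) * n_nodes + seq_len(n_nodes)]] <- u_target[, j]
      }
    }
    if (!is.null(s0)) z[idx$s] <- s0
    z
  }
  # initial-state box bounds become boundary constraints on the chain
  term <- ocp$terminal_constraints
  if (!is.null(ocp$bounds$x0)) {
    n3 <- 3 * ocp$n_q
    lo <- rep_len(ocp$bounds$x0$lower, n3)
    hi <- rep_len(ocp$bounds$x0$upper, n3)
    sc3 <- c(ocp$scale_q, ocp$scale_qd, ocp$scale_qdd)
    val_at0 <- function(tr, k) {
      i <- (k - 1) %% ocp$n_q + 1; g <- (k - 1) %/% ocp$n_q
      M <- if (g == 0) tr$q[[i]] else if (g == 1) tr$qd[[i]] else tr$qdd[[i]]
      M[1, , drop = FALSE]
    }
    k_eq <- which(is.finite(lo) & lo == hi)
    k_in <- which((is.finite(lo) | is.finite(hi)) & !(is.finite(lo) & lo == hi))
    if (length(k_eq)) {
      term$x0_fixed <- list(scale = 1, type = "eq", fn = function(tr)
        do.call(rbind, lapply(k_eq, function(k)
          (val_at0(tr, k) - lo[k]) / sc3[k])))
    }
    if (length(k_in)) {
      term$x0_range <- list(scale = 1, type = "ineq", fn = function(tr)
        do.call(rbind, lapply(k_in, function(k) {
          rows <- NULL
          if (is.finite(lo[k])) rows <- rbind(rows, (lo[k] - val_at0(tr, k)) / sc3[k])
          if (is.finite(hi[k])) rows <- rbind(rows, (val_at0(tr, k) - hi[k]) / sc3[k])
          rows
        })))
    }
  }
  blocks_fn <- function(Zs) {   # scaled variables
    Z <- Zs * z_scale
    traj <- unpack(Z)
    m <- traj$m
    cost <- matrix(0, 0, m)
    for (ct in ocp$cost_terms) {
      if (ct$weight == 0) next
      cost <- rbind(cost, sqrt(ct$weight) * ct$fn(traj))
    }
    eq <- list(); ineq <- list()
    grab <- function(spec, name) {
      v <- spec$fn(traj) / spec$scale
      if (spec$type == "eq") eq[[name]] <<- v else ineq[[name]] <<- v
    }
    for (nm in names(ocp$path_constraints)) grab(ocp$path_constraints[[nm]], nm)
    for (nm in names(term)) grab(term[[nm]], nm)
    for (nm in names(ocp$periodicity)) {
      p <- ocp$periodicity[[nm]]
      v <- p$fn(traj)
      eq[[paste0("periodicity.", nm)]] <-
        (v[nrow(v), , drop = FALSE] - v[1, , drop = FALSE] - p$shift) / p$scale
    }
    list(cost = cost, eq = eq, ineq = ineq)
  }
  expand_bounds <- function(group, width, default = Inf) {
    b <- ocp$bounds[[group]]
    if (is.null(b)) return(list(lower = rep(-default, width), upper = rep(default, width)))
    list(lower = rep_len(b$lower, width), upper = rep_len(b$upper, width))
  }
  bu <- expand_bounds("u", max(ocp$n_u, 1))
  bs <- expand_bounds("s", max(ocp$n_s, 1))
  lower <- c(rep(-Inf, n_y),
             rep(bu$lower[seq_len(ocp$n_u)], each = n_nodes),
             bs$lower[seq_len(ocp$n_s)]) / z_scale
  upper <- c(rep(Inf, n_y),
             rep(bu$upper[seq_len(ocp$n_u)], each = n_nodes),
             bs$upper[seq_len(ocp$n_s)]) / z_scale
  info <- list(
    n_var = nz, n_collocation_points = cm$np,
    n_defects_eliminated = 3L * ocp$n_q * ocp$N,
    n_path_constraints = length(ocp$path_constraints),
    n_path_rows_nominal = length(ocp$path_constraints) * n_nodes,
    n_terminal = length(term) + length(ocp$periodicity),
    sparsity = paste("defects eliminated through an orthonormal null-space",
                     "basis; remaining Jacobian dense, by batched forward",
                     "differences"))
  structure(list(ocp = ocp, blocks_fn = blocks_fn, unpack = unpack,
                 make_guess = make_guess, z_scale = z_scale, lower = lower,
                 upper = upper, idx = idx, n_nodes = n_nodes, mesh = cm,
                 chains = cms, info = info),
            class = "ocp_nlp")
}

#' Solve a transcribed optimal control problem
#'
#' Augmented-Lagrangian outer loop over a damped least-squares inner solver;
#' deterministic for identical inputs and options.
#'
#' @param nlp an `ocp_nlp` from [transcribe()].
#' @param z0 initial guess in *physical* units (defaults to zeros/midpoints).
#' @param tol feasibility tolerance on scaled constraints (default 1e-6).
#' @param max_outer,max_inner iteration caps.
#' @param fd_h finite-difference step (scaled variables).
#' @return `ocp_solution`: trajectory (`traj`), static parameters `s`,
#'   `objective`, per-cost-term values, per-constraint max violations,
#'   `status` (`"converged"` iff max scaled violation <= `tol`),
#'   iteration counts, and the raw variable vector `z`.
#' @export
solve_ocp <- function(nlp, z0 = NULL, tol = 1e-6, max_outer = 14,
                      max_inner = 60, fd_h = 1e-6, verbose = FALSE,
                      w0 = 10, w_ramp = 10, w_max = 1e8) {
  nz <- nlp$info$n_var
  if (is.null(z0)) z0 <- numeric(nz)
  z0s <- pmin(pmax(z0 / nlp$z_scale, nlp$lower), nlp$upper)
  fit <- alm_solve(nlp$blocks_fn, z0s, lower = nlp$lower, upper = nlp$upper,
                   tol = tol, outer_max = max_outer, inner_max = max_inner,
                   fd_h = fd_h, verbose = verbose, w0 = w0, w_ramp = w_ramp,
                   w_max = w_max)
  z <- fit$z * nlp$z_scale
  traj <- nlp$unpack(matrix(z, ncol = 1))
  terms <- evaluate_cost_terms_traj(nlp$ocp, traj)
  structure(list(z = z, traj = traj, s = traj$s[, 1],
                 objective = sum(unlist(terms)), cost_terms = terms,
                 violations = fit$viol_by, max_violation = fit$viol,
                 status = fit$status, outer_iterations = fit$outer,
                 inner_iterations = fit$inner_iterations, nlp = nlp),
            class = "ocp_solution")
}

evaluate_cost_terms_traj <- function(ocp, traj) {
  out <- list()
  for (nm in names(ocp$cost_terms)) {
    ct <- ocp$cost_terms[[nm]]
    r <- ct$fn(traj)
    out[[nm]] <- ct$weight * sum(r * r)
  }
  out
}

#' Per-term cost values of a solution
#'
#' Each named cost term evaluated independently on the solution trajectory;
#' their sum equals the reported objective.
#' @param solution an `ocp_solution`. @param ocp the defining
#'   `ocp_definition` (defaults to the one stored in the solution).
#' @return named list of term values.
#' @export
evaluate_cost_terms <- function(solution, ocp = solution$nlp$ocp) {
  evaluate_cost_terms_traj(ocp, solution$traj)
}

#' Periodicity residuals of a solution
#'
#' @param solution an `ocp_solution`.
#' @param pairs names of periodicity pairs (default: all defined).
#' @return named residual vector `value(t_end) - value(0) - shift`.
#' @export
periodicity_residuals <- function(solution, pairs = NULL) {
  defs <- solution$nlp$ocp$periodicity
  if (is.null(pairs)) pairs <- names(defs)
  miss <- setdiff(pairs, names(defs))
  if (length(miss)) stop_gaitfes("unknown periodicity pair(s): ",
                                 paste(miss, collapse = ", "))
  out <- vapply(pairs, function(nm) {
    p <- defs[[nm]]
    v <- p$fn(solution$traj)
    v[nrow(v), 1] - v[1, 1] - p$shift
  }, 0)
  names(out) <- pairs
  out
}
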