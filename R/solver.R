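# Nonlinear least-squares / constrained solve engine.
#
# All residual functions used in this package are "batched": they accept a
# matrix Z (n_var x m) of m candidate points and return the residuals for all
# columns at once (n_res x m). This makes finite-difference Jacobians a single
# function call, which is what keeps a pure-R collocation solver viable.

#' Batched forward-difference Jacobian
#'
#' @param fn batched residual function: matrix (n x m) -> matrix (nr x m).
#' @param z evaluation point (numeric vector).
#' @param r0 optional residual at `z` (first column recomputed otherwise).
#' @param h finite-difference step (applied per variable, relative-ish).
#' @return list(r = residual at z, J = Jacobian nr x n).
#' @keywords internal
fd_jacobian <- function(fn, z, r0 = NULL, h = 1e-6) {
  n <- length(z)
  hh <- h * (1 + abs(z))
  Z <- matrix(z, n, n + 1)
  Z[, -1] <- Z[, -1] + diag(hh, n)
  R <- fn(Z)
  r0 <- R[, 1]
  J <- (R[, -1, drop = FALSE] - r0) / rep(hh, each = nrow(R))
  list(r = r0, J = J)
}

#' Levenberg-Marquardt on a batched residual function
#'
#' Minimizes `0.5 * ||fn(z)||^2` subject to optional box bounds (handled by
#' clamping trial steps). Deterministic: no randomness, fixed tie-breaks.
#'
#' @param fn batched residual function (see [fd_jacobian()]).
#' @param z0 start point.
#' @param lower,upper optional bounds (recycled).
#' @param max_iter iteration cap.
#' @param ftol relative cost-decrease tolerance.
#' @param xtol step-size tolerance.
#' @param fd_h finite-difference step.
#' @param lambda0 initial damping.
#' @return list with `z`, `residual`, `cost`, `iterations`, `converged`.
#' @keywords internal
lm_solve <- function(fn, z0, lower = NULL, upper = NULL, max_iter = 100,
                     ftol = 1e-10, xtol = 1e-10, fd_h = 1e-6, lambda0 = 1e-3) {
  n <- length(z0)
  lo <- if (is.null(lower)) rep(-Inf, n) else rep_len(lower, n)
  hi <- if (is.null(upper)) rep(Inf, n) else rep_len(upper, n)
  z <- pmin(pmax(z0, lo), hi)
  lam <- lambda0
  fj <- fd_jacobian(fn, z, h = fd_h)
  r <- fj$r; J <- fj$J
  cost <- 0.5 * sum(r * r)
  iter <- 0L; converged <- FALSE
  # bound-constrained damped step: active-set passes fix variables whose
  # unconstrained step exits the box (step to the bound, re-solve the rest)
  bounded_step <- function(JtJ, g, d, lam) {
    free <- lo < hi
    step <- numeric(n)
    for (pass in 1:6) {
      idx_f <- which(free)
      if (!length(idx_f)) break
      A <- JtJ[idx_f, idx_f, drop = FALSE] + diag(lam * d[idx_f], length(idx_f))
      gf <- g[idx_f]
      fixed <- which(!free & (lo < hi))
      if (length(fixed))
        gf <- gf + JtJ[idx_f, fixed, drop = FALSE] %*% step[fixed]
      sf <- tryCatch(-solve(A, gf), error = function(e) NULL)
      if (is.null(sf)) return(NULL)
      step[idx_f] <- sf
      out <- (z + step < lo - 1e-15) | (z + step > hi + 1e-15)
      hit <- out & free
      if (!any(hit)) break
      step[hit] <- pmin(pmax(z[hit] + step[hit], lo[hit]), hi[hit]) - z[hit]
      free[hit] <- FALSE
    }
    step
  }
  while (iter < max_iter) {
    iter <- iter + 1L
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    d <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    for (k in 1:30) {
      step <- bounded_step(JtJ, g, d, lam)
      if (is.null(step)) { lam <- lam * 10; next }
      # evaluate full and backtracked fractions of the step in one batch
      fracs <- c(1, 0.5, 0.25)
      Zt <- vapply(fracs, function(f)
        pmin(pmax(z + f * as.numeric(step), lo), hi), numeric(n))
      Rt <- fn(Zt)
      costs <- 0.5 * colSums(Rt * Rt)
      best <- which.min(costs)
      if (is.finite(costs[best]) && costs[best] <= cost) {
        z_new <- Zt[, best]
        dz <- sqrt(sum((z_new - z)^2) / max(1, sum(z * z)))
        rel_drop <- (cost - costs[best]) / max(cost, 1e-300)
        z <- z_new; accepted <- TRUE
        lam <- if (best == 1) max(lam / 3, 1e-12) else lam * 2
        fj <- fd_jacobian(fn, z, h = fd_h)
        r <- fj$r; J <- fj$J; cost <- 0.5 * sum(r * r)
        if (rel_drop < ftol || dz < xtol) converged <- TRUE
        break
      }
      lam <- lam * 4
    }
    if (!accepted) { converged <- TRUE; break }  # stalled at (local) optimum
    if (converged) break
  }
  list(z = z, residual = r, cost = cost, iterations = iter, converged = converged)
}

#' Augmented-Lagrangian solve over named residual blocks
#'
#' The problem is given by a single batched function returning, for each
#' candidate column, three residual groups:
#' \itemize{
#'   \item `cost`: least-squares cost residuals (minimized),
#'   \item `eq`: named list of equality-constraint matrices (driven to 0),
#'   \item `ineq`: named list of inequality matrices (driven to <= 0).
#' }
#' Constraints should be pre-scaled by the caller to O(1) characteristic
#' magnitudes; `tol` is interpreted on that scale. Equalities get multiplier
#' estimates `lambda`, inequalities shifted hinge penalties with multipliers
#' `mu >= 0`; the penalty weight is increased tenfold whenever an outer
#' iteration fails to cut the maximum violation by 4x.
#'
#' @param blocks_fn batched function: matrix (n x m) -> list(cost, eq, ineq).
#' @param z0 start point.
#' @param lower,upper optional box bounds.
#' @param tol feasibility tolerance on scaled constraints.
#' @param w0 initial penalty weight.
#' @param outer_max outer iteration cap.
#' @param inner_max LM iterations per outer step.
#' @param fd_h finite-difference step.
#' @return list with `z`, `cost` (0.5*||cost residual||^2), `viol` (max scaled
#'   violation), `viol_by` (named per-block max violation), `status`
#'   (`"converged"` or `"tolerance_not_met"`), `outer`, `inner_iterations`.
#' @keywords internal
alm_solve <- function(blocks_fn, z0, lower = NULL, upper = NULL, tol = 1e-6,
                      w0 = 10, w_ramp = 10, w_max = 1e8, outer_max = 14,
                      inner_max = 60, fd_h = 1e-6, verbose = FALSE) {
  probe <- blocks_fn(matrix(z0, ncol = 1))
  eq_dims <- vapply(probe$eq, nrow, 1L)
  in_dims <- vapply(probe$ineq, nrow, 1L)
  ne <- sum(eq_dims); ni <- sum(in_dims)
  lam <- numeric(ne); mu <- numeric(ni)
  w <- w0
  stack <- function(Z) {
    b <- blocks_fn(Z)
    eqm <- if (ne) do.call(rbind, b$eq) else matrix(0, 0, ncol(Z))
    inm <- if (ni) do.call(rbind, b$ineq) else matrix(0, 0, ncol(Z))
    rbind(b$cost,
          if (ne) sqrt(w) * (eqm + lam / w),
          if (ni) sqrt(w) * pmax(inm + mu / w, 0))
  }
  z <- z0
  viol_prev <- Inf
  total_inner <- 0L
  eval_viol <- function(z) {
    b <- blocks_fn(matrix(z, ncol = 1))
    eqv <- if (ne) vapply(b$eq, function(m) max(abs(m)), 0) else numeric(0)
    inv <- if (ni) vapply(b$ineq, function(m) max(c(m, 0)), 0) else numeric(0)
    list(b = b, by = c(eqv, inv),
         eq = if (ne) do.call(rbind, b$eq)[, 1] else numeric(0),
         ineq = if (ni) do.call(rbind, b$ineq)[, 1] else numeric(0))
  }
  outer <- 0L
  repeat {
    outer <- outer + 1L
    fit <- lm_solve(stack, z, lower = lower, upper = upper,
                    max_iter = inner_max, fd_h = fd_h)
    z <- fit$z
    total_inner <- total_inner + fit$iterations
    vv <- eval_viol(z)
    viol <- if (length(vv$by)) max(vv$by) else 0
    if (verbose)
      message(sprintf("  outer %2d: w=%.1e inner=%3d cost=%.4g viol=%.3e [%s]",
                      outer, w, fit$iterations, 0.5 * sum(vv$b$cost^2), viol,
                      names(which.max(vv$by))))
    if (viol <= tol || outer >= outer_max) break
    lam <- lam + w * vv$eq
    mu <- pmax(0, mu + w * vv$ineq)
    if (viol > 0.25 * viol_prev) w <- min(w * w_ramp, w_max)
    viol_prev <- viol
  }
  vv <- eval_viol(z)
  viol <- if (length(vv$by)) max(vv$by) else 0
  list(z = z, cost = 0.5 * sum(vv$b$cost^2), viol = viol, viol_by = vv$by,
       status = if (viol <= tol) "converged" else "tolerance_not_met",
       outer = outer, inner_iterations = total_inner)
}
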