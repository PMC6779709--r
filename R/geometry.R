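# Surrogate musculoskeletal geometry: straight-line muscle path models and
# polynomial fits of muscle-tendon length / moment arms over joint ranges.
#
# The surrogate enforces the differential consistency r_j = -d(l_mt)/dq_j by
# construction: lengths and moment arms are fitted *jointly* with shared
# polynomial coefficients, the moment-arm rows using the analytic derivative
# of the length basis.

#' Muscle-tendon length of a geometric path model
#'
#' Straight-line segments between ordered attachment/via points fixed in body
#' segment frames.
#'
#' @param skel a `planar_skeleton`.
#' @param path path spec: `list(name, spans, points)` where each point is
#'   `list(segment, p = c(x, y))` in the segment frame.
#' @param q coordinate vector, or array (n_time x n_case x 11) for batched use.
#' @return length in m (scalar or matrix matching the batch shape).
#' @export
path_length <- function(skel, path, q) {
  qa <- as_coord_array(q)
  fk <- fk_batched(skel, qa)
  xs <- ys <- vector("list", length(path$points))
  for (i in seq_along(path$points)) {
    pt <- path$points[[i]]
    pp <- rot2(fk[[pt$segment]]$th, pt$p[1], pt$p[2])
    xs[[i]] <- fk[[pt$segment]]$ox + pp$x
    ys[[i]] <- fk[[pt$segment]]$oy + pp$y
  }
  len <- 0
  for (i in seq_len(length(path$points) - 1)) {
    len <- len + sqrt((xs[[i + 1]] - xs[[i]])^2 + (ys[[i + 1]] - ys[[i]])^2)
  }
  if (is.array(q) && length(dim(q)) == 3) len else len[1, 1]
}

#' Moment arms of a path model by central differences
#'
#' Independent geometric oracle: `r_j = -d(l_mt)/dq_j` evaluated numerically
#' on the path model itself.
#'
#' @inheritParams path_length
#' @param h finite-difference step (rad).
#' @return named vector of moment arms (m) over the spanned coordinates.
#' @export
path_moment_arms <- function(skel, path, q, h = 1e-6) {
  out <- numeric(length(path$spans))
  for (j in seq_along(path$spans)) {
    i <- coord_index(skel, path$spans[j])
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    out[j] <- -(path_length(skel, path, qp) - path_length(skel, path, qm)) / (2 * h)
  }
  names(out) <- path$spans
  out
}

poly_powers <- function(nd, degree) {
  grid <- do.call(expand.grid, rep(list(0:degree), nd))
  grid <- as.matrix(grid[rowSums(grid) <= degree, , drop = FALSE])
  grid[order(rowSums(grid), grid[, 1]), , drop = FALSE]
}

#' Fit polynomial surrogate geometry for one muscle
#'
#' Samples the path model over a grid covering the joint ranges and fits a
#' single polynomial in the spanned joint angles whose value approximates the
#' muscle-tendon length and whose negative partial derivatives approximate the
#' moment arms (joint least squares over both sets of rows).
#'
#' @param skel a `planar_skeleton`.
#' @param path path spec (see [path_length()]).
#' @param joint_ranges named list of `c(lo, hi)` (rad) for each spanned DOF.
#' @param degree total polynomial degree, >= 2.
#' @param n_grid samples per DOF.
#' @param q_ref reference pose for the unspanned coordinates.
#' @return object of class `surrogate_geometry`: coefficients, powers,
#'   centering/scaling, ranges, and max fit residuals.
#' @export
fit_surrogate_geometry <- function(skel, path, joint_ranges, degree = 4,
                                   n_grid = NULL, q_ref = rep(0, length(skel$coords))) {
  if (degree < 2) stop_gaitfes("degree must be >= 2")
  spans <- path$spans
  nd <- length(spans)
  if (is.null(n_grid)) n_grid <- if (nd == 1) 15L else 9L
  rng <- lapply(spans, function(s) {
    r <- joint_ranges[[s]] %||% joint_ranges[[sub("_[rl]$", "", s)]]
    if (is.null(r)) stop_gaitfes("no joint range given for ", s)
    r
  })
  names(rng) <- spans
  mid <- vapply(rng, mean, 0)
  hw <- vapply(rng, function(r) (r[2] - r[1]) / 2, 0)
  grid <- do.call(expand.grid, lapply(rng, function(r) seq(r[1], r[2], length.out = n_grid)))
  n_s <- nrow(grid)
  idx <- vapply(spans, coord_index, 1L, skel = skel)
  qa <- array(rep(q_ref, each = n_s), c(n_s, 1, length(skel$coords)))
  for (j in seq_len(nd)) qa[, 1, idx[j]] <- grid[[j]]
  len <- path_length(skel, path, qa)[, 1]
  h <- 1e-5
  arms <- matrix(0, n_s, nd)
  for (j in seq_len(nd)) {
    qp <- qa; qp[, 1, idx[j]] <- qp[, 1, idx[j]] + h
    qm <- qa; qm[, 1, idx[j]] <- qm[, 1, idx[j]] - h
    arms[, j] <- -(path_length(skel, path, qp)[, 1] -
                   path_length(skel, path, qm)[, 1]) / (2 * h)
  }
  pw <- poly_powers(nd, degree)
  nb <- nrow(pw)
  U <- sweep(sweep(as.matrix(grid), 2, mid), 2, hw, "/")
  B <- matrix(1, n_s, nb)
  for (j in seq_len(nd)) B <- B * outer(U[, j], pw[, j], `^`)
  rows <- list(B)
  rhs <- list(len)
  for (j in seq_len(nd)) {
    D <- matrix(0, n_s, nb)
    for (b in seq_len(nb)) {
      if (pw[b, j] == 0) next
      term <- rep(pw[b, j] / hw[j], n_s)
      for (jj in seq_len(nd)) {
        e <- pw[b, jj] - (jj == j)
        term <- term * U[, jj]^e
      }
      D[, b] <- term
    }
    rows[[j + 1]] <- D        # -d(len)/dq_j rows must equal arm_j: arm = -D c
    rhs[[j + 1]] <- -arms[, j]
  }
  A <- do.call(rbind, rows)
  y <- unlist(rhs)
  qrA <- qr(A)
  if (qrA$rank < nb) {
    d <- svd(A, nu = 0, nv = 0)$d
    stop_gaitfes("ill-conditioned surrogate fit (rank ", qrA$rank, " < ", nb,
                 "; condition number ", format(d[1] / max(d[length(d)], 1e-300),
                                               digits = 3), ")")
  }
  coef <- qr.coef(qrA, y)
  fit_len <- B %*% coef
  res_len <- max(abs(fit_len - len))
  res_arm <- 0
  for (j in seq_len(nd)) {
    res_arm <- max(res_arm, max(abs(rows[[j + 1]] %*% coef - rhs[[j + 1]])))
  }
  structure(list(name = path$name, spans = spans, coord_idx = idx, powers = pw,
                 coef = as.numeric(coef), mid = mid, hw = hw, ranges = rng,
                 degree = degree, max_res_len = res_len, max_res_arm = res_arm),
            class = "surrogate_geometry")
}

# Batched surrogate evaluation. q given as list of matrices per spanned DOF.
surrogate_eval_batched <- function(geom, qlist) {
  nd <- length(geom$spans)
  nb <- nrow(geom$powers)
  U <- lapply(seq_len(nd), function(j) (qlist[[j]] - geom$mid[j]) / geom$hw[j])
  len <- 0
  arms <- vector("list", nd)
  for (j in seq_len(nd)) arms[[j]] <- 0
  for (b in seq_len(nb)) {
    term <- geom$coef[b]
    for (j in seq_len(nd)) term <- term * U[[j]]^geom$powers[b, j]
    len <- len + term
    for (j in seq_len(nd)) {
      pj <- geom$powers[b, j]
      if (pj == 0) next
      dterm <- geom$coef[b] * pj / geom$hw[j]
      for (jj in seq_len(nd)) {
        dterm <- dterm * U[[jj]]^(geom$powers[b, jj] - (jj == j))
      }
      arms[[j]] <- arms[[j]] - dterm
    }
  }
  list(len = len, arms = arms)
}

#' Muscle-tendon length, velocity, and moment arms from a surrogate
#'
#' @param q,qdot coordinate and coordinate-rate vectors (length 11).
#' @param geom a `surrogate_geometry`.
#' @param check error if `q` is outside the fitting ranges (default TRUE).
#' @return list with `lmt` (m), `vmt` (m/s, `= -sum_j r_j qdot_j`), and
#'   `arms` (named vector, m).
#' @export
muscle_tendon_kinematics <- function(q, qdot, geom, check = TRUE) {
  qs <- q[geom$coord_idx]
  if (check) {
    for (j in seq_along(geom$spans)) {
      r <- geom$ranges[[j]]
      if (qs[j] < r[1] - 1e-9 || qs[j] > r[2] + 1e-9)
        stop_gaitfes("coordinate ", geom$spans[j], " = ", signif(qs[j], 4),
                     " outside surrogate fitting range [", r[1], ", ", r[2], "]")
    }
  }
  ev <- surrogate_eval_batched(geom, lapply(qs, function(x) matrix(x, 1, 1)))
  arms <- vapply(ev$arms, function(m) m[1, 1], 0)
  names(arms) <- geom$spans
  vmt <- -sum(arms * qdot[geom$coord_idx])
  list(lmt = ev$len[1, 1], vmt = vmt, arms = arms)
}

#' Fit surrogates for a whole muscle set
#'
#' @param skel a `planar_skeleton`.
#' @param muscles output of [default_muscles()] (or same structure).
#' @param joint_ranges named list of ranges; side-suffix-free names
#'   (`hip`, `knee`, `ankle`) apply to both legs.
#' @param degree polynomial degree.
#' @return named list of `surrogate_geometry`.
#' @export
build_surrogates <- function(skel, muscles, joint_ranges = default_joint_ranges(),
                             degree = 4) {
  out <- lapply(muscles$paths, fit_surrogate_geometry, skel = skel,
                joint_ranges = joint_ranges, degree = degree)
  names(out) <- names(muscles$paths)
  out
}

#' Default joint ranges for surrogate fitting (rad)
#' @export
default_joint_ranges <- function() {
  list(hip = c(-0.6, 0.9), knee = c(-0.05, 1.5), ankle = c(-0.7, 0.5))
}
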