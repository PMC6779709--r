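# Planar skeletal model: kinematic tree, batched forward kinematics, and
# generalized-force (inverse-dynamics) evaluation by virtual work.
#
# Conventions: x = direction of progression, y = up, angles CCW-positive in
# radians. The pelvis(+HAT) segment is the floating base with coordinates
# (pelvis_x, pelvis_y, pelvis_tilt). Leg joints are sagittal revolutes with
# flexion/dorsiflexion positive: hip flexion swings the thigh forward (CCW),
# knee flexion folds the shank backward (CW, sign -1), ankle dorsiflexion and
# toe extension lift the toes (CCW). Thigh/shank frames point distally along
# local -y; foot and toe frames point toward the toes along local +x.
#
# Batched evaluation: generalized coordinates are passed as 3-D arrays of
# dimension (n_time, n_case, n_coord) so that finite-difference Jacobians of
# whole trajectories cost a single call.

COORD_NAMES <- c("pelvis_x", "pelvis_y", "pelvis_tilt",
                 "hip_r", "knee_r", "ankle_r", "toe_r",
                 "hip_l", "knee_l", "ankle_l", "toe_l")

#' Construct the default planar skeleton
#'
#' An 11-DOF sagittal-plane model: pelvis+HAT (head-arms-trunk) floating base
#' and per leg a thigh, shank, two-segment foot (hindfoot + toes). Toes are
#' torque-actuated; all other leg joints are muscle-actuated. Dimensions and
#' inertial properties approximate a 75 kg, 1.75 m adult.
#'
#' @param total_mass body mass in kg.
#' @return object of class `planar_skeleton`: list with `segments` (each with
#'   `mass`, `inertia`, `com`, `parent`, `joint_in_parent`, `joint_coord`,
#'   `joint_sign`, `length`), `coords`, `gravity`, and convenience index sets.
#' @export
default_skeleton <- function(total_mass = 75) {
  s <- total_mass / 75
  seg <- function(mass, inertia, com, parent, jip, coord, sign, length)
    list(mass = mass * s, inertia = inertia * s, com = com, parent = parent,
         joint_in_parent = jip, joint_coord = coord, joint_sign = sign,
         length = length)
  leg <- function(side) {
    sfx <- paste0("_", side)
    out <- list(
      seg(7.5, 0.11, c(0, -0.18), "pelvis", c(0, -0.07), paste0("hip", sfx), 1, 0.42),
      seg(3.5, 0.050, c(0, -0.19), paste0("thigh", sfx), c(0, -0.42), paste0("knee", sfx), -1, 0.43),
      seg(1.0, 0.0040, c(0.07, -0.05), paste0("shank", sfx), c(0, -0.43), paste0("ankle", sfx), 1, 0.15),
      seg(0.2, 0.0002, c(0.03, 0.0), paste0("foot", sfx), c(0.15, -0.08), paste0("toe", sfx), 1, 0.07))
    names(out) <- paste0(c("thigh", "shank", "foot", "toe"), sfx)
    out
  }
  segments <- c(
    list(pelvis = seg(50.25, 3.0, c(-0.02, 0.25), NA, NA, NA, NA, 0.60)),
    leg("r"), leg("l"))
  structure(list(
    segments = segments,
    coords = COORD_NAMES,
    gravity = 9.81,
    foot_sole_y = -0.08,      # sole height in hindfoot frame
    mtp_x = 0.15,             # toe joint x in hindfoot frame
    muscle_dofs = c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l"),
    torque_dofs = c("toe_r", "toe_l")
  ), class = "planar_skeleton")
}

check_skeleton <- function(skel) {
  for (nm in names(skel$segments)) {
    sg <- skel$segments[[nm]]
    if (sg$mass <= 0 || sg$inertia <= 0)
      stop_gaitfes("segment '", nm, "': masses and inertias must be > 0")
  }
  invisible(skel)
}

coord_index <- function(skel, name) {
  i <- match(name, skel$coords)
  if (is.na(i)) stop_gaitfes("unknown coordinate '", name, "'")
  i
}

# Segments distal to (and including the child of) each rotational joint.
subtree_segments <- function(skel, coord) {
  segs <- skel$segments
  child <- names(segs)[vapply(segs, function(s) identical(s$joint_coord, coord), TRUE)]
  if (!length(child)) return(character(0))
  out <- child
  repeat {
    more <- names(segs)[vapply(segs, function(s) isTRUE(s$parent %in% out), TRUE)]
    more <- setdiff(more, out)
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

as_coord_array <- function(q, n_coord = length(COORD_NAMES)) {
  if (is.array(q) && length(dim(q)) == 3) return(q)
  if (is.matrix(q)) return(array(q, c(nrow(q), 1L, ncol(q))))  # time x coord
  array(q, c(1L, 1L, n_coord))                                  # single pose
}

arr2 <- function(a, i) matrix(a[, , i], dim(a)[1], dim(a)[2])

#' Batched forward kinematics
#'
#' @param skel a `planar_skeleton`.
#' @param q,qd,qdd coordinate arrays (n_time x n_case x 11); `qd`/`qdd` may be
#'   NULL for position-only evaluation.
#' @return per-segment list with orientation `th`, angular velocity `om`,
#'   angular acceleration `al`, frame-origin position/velocity/acceleration
#'   (`ox,oy,vx,vy,ax,ay`), and COM kinematics (`cx,cy,vcx,vcy,acx,acy`).
#' @keywords internal
fk_batched <- function(skel, q, qd = NULL, qdd = NULL) {
  q <- as_coord_array(q)
  d1 <- dim(q)[1]; d2 <- dim(q)[2]
  zero <- matrix(0, d1, d2)
  if (!is.null(qd)) qd <- as_coord_array(qd)
  if (!is.null(qdd)) qdd <- as_coord_array(qdd)
  gq <- function(a, i) if (is.null(a)) zero else arr2(a, i)
  out <- list()
  # floating base
  th <- arr2(q, 3)
  base <- list(th = th, om = gq(qd, 3), al = gq(qdd, 3),
               ox = arr2(q, 1), oy = arr2(q, 2),
               vx = gq(qd, 1), vy = gq(qd, 2),
               ax = gq(qdd, 1), ay = gq(qdd, 2))
  finish <- function(k, sg) {
    cc <- rot2(k$th, sg$com[1], sg$com[2])
    k$cx <- k$ox + cc$x; k$cy <- k$oy + cc$y
    k$vcx <- k$vx - k$om * cc$y; k$vcy <- k$vy + k$om * cc$x
    k$acx <- k$ax - k$al * cc$y - k$om^2 * cc$x
    k$acy <- k$ay + k$al * cc$x - k$om^2 * cc$y
    k
  }
  out$pelvis <- finish(base, skel$segments$pelvis)
  for (nm in names(skel$segments)[-1]) {
    sg <- skel$segments[[nm]]
    p <- out[[sg$parent]]
    i <- coord_index(skel, sg$joint_coord)
    d <- rot2(p$th, sg$joint_in_parent[1], sg$joint_in_parent[2])
    k <- list(
      th = p$th + sg$joint_sign * arr2(q, i),
      om = p$om + sg$joint_sign * gq(qd, i),
      al = p$al + sg$joint_sign * gq(qdd, i),
      ox = p$ox + d$x, oy = p$oy + d$y,
      vx = p$vx - p$om * d$y, vy = p$vy + p$om * d$x,
      ax = p$ax - p$al * d$y - p$om^2 * d$x,
      ay = p$ay + p$al * d$x - p$om^2 * d$y)
    out[[nm]] <- finish(k, sg)
  }
  out
}

#' Kinematics of a point fixed in a segment frame
#' @keywords internal
segment_point_kin <- function(fk_seg, px, py) {
  pp <- rot2(fk_seg$th, px, py)
  list(x = fk_seg$ox + pp$x, y = fk_seg$oy + pp$y,
       vx = fk_seg$vx - fk_seg$om * pp$y, vy = fk_seg$vy + fk_seg$om * pp$x,
       ax = fk_seg$ax - fk_seg$al * pp$y - fk_seg$om^2 * pp$x,
       ay = fk_seg$ay + fk_seg$al * pp$x - fk_seg$om^2 * pp$y)
}

# Generalized forces required to produce (q, qd, qdd) given external point
# loads: tau_req_i = sum_s [ m_s (a_com,s - g) . Jv_{s,i} + I_s alpha_s Jw_{s,i} ]
#                    - sum_loads F . Jv_i(point).
# `loads` is a list of entries: list(segment=, px=, py= (local) OR x=, y=
# (world, matrices), fx=, fy= (matrices)). Virtual-work Jacobians come from
# the joint positions in `fk`.
inverse_generalized_forces <- function(skel, fk, loads = list(), gravity = skel$gravity) {
  d1 <- nrow(fk$pelvis$th); d2 <- ncol(fk$pelvis$th)
  nq <- length(skel$coords)
  tau <- vector("list", nq)
  zero <- matrix(0, d1, d2)
  for (i in seq_len(nq)) tau[[i]] <- zero
  seg_names <- names(skel$segments)
  # inertial + gravity wrench per segment applied at its COM:
  # F_s = m (a_com - g), T_s = I * alpha
  load_pts <- lapply(loads, function(L) {
    if (!is.null(L$px)) {
      pk <- segment_point_kin(fk[[L$segment]], L$px, L$py)
      list(segment = L$segment, x = pk$x, y = pk$y, fx = L$fx, fy = L$fy)
    } else list(segment = L$segment, x = L$x, y = L$y, fx = L$fx, fy = L$fy)
  })
  add_dof <- function(i, jx, jy, sign_) {
    # rotational DOF i with joint world position (jx, jy): Jv = sign*perp(r - r_j)
    acc <- zero
    subtree <- if (i == 3L) seg_names else subtree_segments(skel, skel$coords[i])
    for (nm in subtree) {
      sg <- skel$segments[[nm]]; k <- fk[[nm]]
      fx <- sg$mass * k$acx
      fy <- sg$mass * (k$acy + gravity)
      acc <- acc + fx * (-(k$cy - jy)) + fy * (k$cx - jx) + sg$inertia * k$al
    }
    for (L in load_pts) {
      if (!(L$segment %in% subtree)) next
      # external loads act on the system; subtract their generalized force
      acc <- acc - (L$fx * (-(L$y - jy)) + L$fy * (L$x - jx))
    }
    tau[[i]] <<- tau[[i]] + sign_ * acc
  }
  # translations: Jv = e_x / e_y for every segment
  for (nm in seg_names) {
    sg <- skel$segments[[nm]]; k <- fk[[nm]]
    tau[[1]] <- tau[[1]] + sg$mass * k$acx
    tau[[2]] <- tau[[2]] + sg$mass * (k$acy + gravity)
  }
  for (L in load_pts) {
    tau[[1]] <- tau[[1]] - L$fx
    tau[[2]] <- tau[[2]] - L$fy
  }
  # pelvis tilt: rotation of everything about the pelvis frame origin
  add_dof(3L, fk$pelvis$ox, fk$pelvis$oy, 1)
  for (i in seq_len(nq)[-(1:3)]) {
    cname <- skel$coords[i]
    child <- names(skel$segments)[vapply(skel$segments,
              function(s) identical(s$joint_coord, cname), TRUE)]
    k <- fk[[child]]
    add_dof(i, k$ox, k$oy, skel$segments[[child]]$joint_sign)
  }
  array(unlist(tau), c(d1, d2, nq))
}

#' Skeletal dynamics residual
#'
#' Evaluates `M(q) qdd + c(q, qd) + g(q) - tau - J^T F_ext` for one state.
#' A zero residual means the state, applied moments, and external forces are
#' dynamically consistent.
#'
#' @param skel a `planar_skeleton`.
#' @param q,qd,qdd coordinate vectors (length 11).
#' @param applied_moments generalized applied forces (length 11; pelvis
#'   entries are normally 0 since the base is unactuated).
#' @param external_forces list of point loads, each
#'   `list(segment=, px=, py=, fx=, fy=)` with `px`,`py` in the segment frame
#'   and forces in the ground frame.
#' @return residual vector (length 11, N or N m per coordinate).
#' @export
skeleton_dynamics_residual <- function(skel, q, qd, qdd,
                                       applied_moments = numeric(length(skel$coords)),
                                       external_forces = list()) {
  check_skeleton(skel)
  M <- mass_matrix(skel, q)
  if (abs(det(M)) < 1e-12)
    stop_gaitfes("singular mass matrix: degenerate inertia input")
  loads <- lapply(external_forces, function(L) {
    list(segment = L$segment, px = L$px, py = L$py,
         fx = matrix(L$fx, 1, 1), fy = matrix(L$fy, 1, 1))
  })
  fk <- fk_batched(skel, as_coord_array(q), as_coord_array(qd), as_coord_array(qdd))
  tau_req <- inverse_generalized_forces(skel, fk, loads)
  as.numeric(tau_req[1, 1, ]) - applied_moments
}

#' Mass matrix M(q)
#'
#' Assembled column-by-column from the inverse-dynamics operator with unit
#' accelerations and gravity switched off.
#'
#' @param skel a `planar_skeleton`. @param q coordinate vector.
#' @return 11 x 11 symmetric positive-definite matrix.
#' @export
mass_matrix <- function(skel, q) {
  nq <- length(skel$coords)
  qa <- array(rep(q, each = nq), c(nq, 1, nq))   # nq cases stacked in time dim
  qz <- array(0, c(nq, 1, nq))
  qdd <- array(0, c(nq, 1, nq))
  for (k in seq_len(nq)) qdd[k, 1, k] <- 1
  fk <- fk_batched(skel, qa, qz, qdd)
  tau <- inverse_generalized_forces(skel, fk, gravity = 0)
  M <- matrix(tau[, 1, ], nq, nq)   # row k = tau for unit qdd_k -> M[k, ] = col k
  t(M)
}

#' Velocity-product and gravity bias c(q,qd) + g(q)
#' @keywords internal
bias_forces <- function(skel, q, qd) {
  fk <- fk_batched(skel, as_coord_array(q), as_coord_array(qd), NULL)
  as.numeric(inverse_generalized_forces(skel, fk)[1, 1, ])
}

#' Forward dynamics: accelerations from applied generalized forces
#' @keywords internal
forward_dynamics <- function(skel, q, qd, tau = numeric(length(skel$coords))) {
  solve(mass_matrix(skel, q), tau - bias_forces(skel, q, qd))
}

#' Total mechanical energy (kinetic + gravitational potential)
#' @keywords internal
mechanical_energy <- function(skel, q, qd) {
  fk <- fk_batched(skel, as_coord_array(q), as_coord_array(qd), NULL)
  e <- 0
  for (nm in names(skel$segments)) {
    sg <- skel$segments[[nm]]; k <- fk[[nm]]
    e <- e + 0.5 * sg$mass * (k$vcx[1, 1]^2 + k$vcy[1, 1]^2) +
      0.5 * sg$inertia * k$om[1, 1]^2 + sg$mass * skel$gravity * k$cy[1, 1]
  }
  e
}
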