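# Shared machinery for the gait optimal control problems: every
# personalization and treatment problem couples the same evaluation pipeline
# (forward kinematics -> muscle geometry -> synergy-driven muscle forces ->
# foot-ground contact -> inverse skeletal dynamics) to different cost terms,
# constraints, and static parameters.
#
# The pipeline is evaluated at mesh nodes and memoized per trajectory batch:
# cost and constraint closures all receive the same `traj` object, so the
# first caller computes the pipeline and the rest reuse it.

#' Assemble a gait model container
#'
#' @param skel a `planar_skeleton`.
#' @param muscles muscle set (paths + params), see [default_muscles()].
#' @param surrogates fitted surrogate geometry, see [build_surrogates()].
#' @param contact a `contact_params`.
#' @param elements a `contact_element_set`.
#' @param W synergy vector matrix per leg: list(r = 9 x n_syn, l = ...),
#'   non-negative, or NULL before neural calibration.
#' @param t_end gait cycle duration (s).
#' @param belt_speed treadmill belt speed / progression speed (m/s).
#' @param n_syn synergies per leg.
#' @param emg_status named character: "measured", "copied", or "predicted"
#'   per muscle.
#' @return `gait_model` list with derived index tables.
#' @export
gait_model <- function(skel, muscles, surrogates, contact, elements,
                       W = NULL, t_end = 1.2, belt_speed = 0.6, n_syn = 3,
                       emg_status = NULL) {
  mnames <- names(muscles$params)
  sides <- ifelse(grepl("_r$", mnames), "r", "l")
  if (is.null(emg_status)) {
    base <- sub("_[rl]$", "", mnames)
    emg_status <- ifelse(base %in% c("iliopsoas", "bifemsh"), "predicted", "measured")
    names(emg_status) <- mnames
  }
  mdofs <- match(c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l"),
                 skel$coords)
  toe_dofs <- match(c("toe_r", "toe_l"), skel$coords)
  structure(list(skel = skel, muscles = muscles, surrogates = surrogates,
                 contact = contact, elements = elements, W = W,
                 t_end = t_end, belt_speed = belt_speed, n_syn = n_syn,
                 muscle_names = mnames, muscle_side = sides,
                 emg_status = emg_status, mdofs = mdofs, toe_dofs = toe_dofs),
            class = "gait_model")
}

muscles_of_side <- function(model, side) which(model$muscle_side == side)

# row-subset matrices of a trajectory as a coordinate array (nn x m x 11)
nodes_array <- function(traj, field, rows = traj$node_idx) {
  lst <- lapply(traj[[field]], function(M) M[rows, , drop = FALSE])
  array(unlist(lst), c(length(rows), ncol(lst[[1]]), length(lst)))
}

# trapezoid weights over the node grid
node_quad_w <- function(traj) {
  tn <- traj$t[traj$node_idx]
  h <- diff(tn)
  w <- c(h, 0) / 2 + c(0, h) / 2
  w
}

#' Evaluate the gait pipeline on a trajectory batch (memoized)
#'
#' @param model a `gait_model`.
#' @param traj trajectory batch from the transcribed problem.
#' @param opts list controlling sources:
#'   `muscle_driven` (logical), `contact_source` ("model"/"static"),
#'   `contact_static_idx` (rows of `traj$s` holding stiffness, damping, mu_d,
#'   mu_v), `W_source` ("model"/"static"), `W_static_idx`,
#'   `stim` (NULL or list(muscle_idx, shapes, static_rows)).
#' @return list with node kinematics, activations, muscle forces/moments,
#'   per-foot ground reactions, and required generalized forces `tau`.
#' @keywords internal
gait_pipeline <- function(model, traj, opts) {
  if (!is.null(traj$cache$gait)) return(traj$cache$gait)
  skel <- model$skel
  # eval_all: evaluate at midpoints too (hard constraints stay at nodes;
  # midpoints feed soft dynamics costs and Simpson-quadrature metrics)
  ni <- if (isTRUE(opts$eval_all)) seq_len(traj$np) else traj$node_idx
  nn <- length(ni); m <- traj$m
  is_node <- ni %in% traj$node_idx
  qa <- nodes_array(traj, "q", ni); qda <- nodes_array(traj, "qd", ni)
  qdda <- nodes_array(traj, "qdd", ni)
  fkn <- fk_batched(skel, qa, qda, qdda)
  # contact parameters, possibly from static decision variables
  cp <- model$contact
  if (identical(opts$contact_source, "static")) {
    ridx <- opts$contact_static_idx
    as_mat <- function(r) matrix(traj$s[r, ], nn, m, byrow = TRUE)
    cp <- model$contact
    # stiffness is carried in log10 (it spans decades)
    cp$stiffness <- 10^as_mat(ridx[1]); cp$damping <- as_mat(ridx[2])
    cp$mu_d <- as_mat(ridx[3]); cp$mu_v <- as_mat(ridx[4])
  }
  fc_r <- foot_contact_batched(skel, fkn, model$elements, cp, "r")
  fc_l <- foot_contact_batched(skel, fkn, model$elements, cp, "l")
  out <- list(nn = nn, m = m, t_nodes = traj$t[ni], fkn = fkn,
              rows = ni, node_rows = which(is_node),
              mid_rows = which(!is_node),
              grf = list(r = fc_r, l = fc_l))
  muscle_forces <- NULL; act <- NULL
  if (isTRUE(opts$muscle_driven)) {
    # synergy vectors
    if (identical(opts$W_source, "static")) {
      Wr_rows <- opts$W_static_idx$r; Wl_rows <- opts$W_static_idx$l
      Wmat <- function(rows) traj$s[rows, , drop = FALSE]  # (9*n_syn) x m
      Wr <- Wmat(Wr_rows); Wl <- Wmat(Wl_rows)
    } else {
      Wr <- matrix(model$W$r, ncol = 1); Wl <- matrix(model$W$l, ncol = 1)
    }
    n_syn <- model$n_syn
    # synergy activations: controls 1..n_syn right leg, then left leg
    Cn <- lapply(seq_len(2 * n_syn), function(k) traj$u[[k]][ni, , drop = FALSE])
    act <- vector("list", length(model$muscle_names))
    for (mi in seq_along(model$muscle_names)) {
      side <- model$muscle_side[mi]
      pos <- if (side == "r") match(mi, muscles_of_side(model, "r"))
             else match(mi, muscles_of_side(model, "l"))
      Wm <- if (side == "r") Wr else Wl
      off <- if (side == "r") 0 else n_syn
      a <- 0
      for (k in seq_len(n_syn)) {
        wrow <- Wm[(k - 1) * 9 + pos, ]           # scalar or length-m
        if (length(wrow) == 1) {
          a <- a + wrow * Cn[[off + k]]
        } else {
          a <- a + matrix(wrow, nn, m, byrow = TRUE) * Cn[[off + k]]
        }
      }
      act[[mi]] <- a
    }
    # electrical stimulation on selected muscles (statics: A, t_on, duration)
    a_stim <- vector("list", length(model$muscle_names))
    if (!is.null(opts$stim)) {
      tn <- traj$t[ni]
      for (j in seq_along(opts$stim$muscle_idx)) {
        mi <- opts$stim$muscle_idx[j]
        rows <- opts$stim$static_rows[[j]]
        A <- matrix(traj$s[rows[1], ], nn, m, byrow = TRUE)
        t_on <- matrix(traj$s[rows[2], ], nn, m, byrow = TRUE)
        dur <- matrix(traj$s[rows[3], ], nn, m, byrow = TRUE)
        sh <- opts$stim$shapes[[j]]
        tt <- matrix(tn, nn, m)
        t_off_u <- t_on + dur
        a_s <- A / 2 * (tanh(sh$c1 * (tt - t_on - sh$t_offset1)) -
                        tanh(sh$c2 * (tt - t_off_u - sh$t_offset2))) +
               A / 2 * (1 - tanh(sh$c2 * (tt - t_off_u - sh$t_offset2 + traj$t_end)))
        a_stim[[mi]] <- a_s
        act[[mi]] <- act[[mi]] + a_s
      }
    }
    out$a_stim <- a_stim
    # muscle-tendon kinematics + Hill forces + joint moments
    Mmus <- rep(list(0), length(skel$coords))
    muscle_forces <- vector("list", length(model$muscle_names))
    for (mi in seq_along(model$muscle_names)) {
      geom <- model$surrogates[[model$muscle_names[mi]]]
      qlist <- lapply(geom$coord_idx, function(i) traj$q[[i]][ni, , drop = FALSE])
      ev <- surrogate_eval_batched(geom, qlist)
      vmt <- 0
      for (j in seq_along(geom$coord_idx)) {
        vmt <- vmt - ev$arms[[j]] * traj$qd[[geom$coord_idx[j]]][ni, , drop = FALSE]
      }
      Fm <- hill_force_batched(act[[mi]], ev$len, vmt,
                               model$muscles$params[[model$muscle_names[mi]]])
      muscle_forces[[mi]] <- Fm
      for (j in seq_along(geom$coord_idx)) {
        ci <- geom$coord_idx[j]
        Mmus[[ci]] <- Mmus[[ci]] + ev$arms[[j]] * Fm
      }
    }
    out$act <- act
    out$muscle_forces <- muscle_forces
    out$Mmus <- Mmus
  }
  out$tau <- inverse_generalized_forces(skel, fkn, c(fc_r$loads, fc_l$loads))
  traj$cache$gait <- out
  out
}

# --- common residual-block builders ----------------------------------------

.dyn_scales <- c(force = 750, moment = 150)

# pelvis (unactuated floating-base) dynamics equations at nodes
pelvis_residual_fn <- function(model, opts) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$node_rows
    rbind(matrix(g$tau[, , 1], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[1],
          matrix(g$tau[, , 2], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[1],
          matrix(g$tau[, , 3], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[2])
  }
}

# synergy-generated joint moments must match the inverse-dynamics moments
moment_match_fn <- function(model, opts) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$node_rows
    do.call(rbind, lapply(model$mdofs, function(ci)
      (matrix(g$tau[, , ci], g$nn, g$m)[r, , drop = FALSE] -
         g$Mmus[[ci]][r, , drop = FALSE]) / 100))
  }
}

# fore-aft (pelvis_x) dynamics imposed at the midpoints as well: the signed
# between-node residual of this equation is exactly what makes the net
# fore-aft impulse of a periodic cycle drift away from zero, so it is held
# to the solver tolerance everywhere (requires opts$eval_all)
pelvis_x_mid_fn <- function(model, opts) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$mid_rows
    if (!length(r)) return(matrix(0, 0, g$m))
    matrix(g$tau[, , 1], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[1]
  }
}

# soft midpoint dynamics: the same residuals evaluated between the nodes,
# as a cost term — damps inter-node oscillation that node-only collocation
# would otherwise admit (requires opts$eval_all)
mid_dynamics_fn <- function(model, opts, with_moments = TRUE) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$mid_rows
    if (!length(r)) return(matrix(0, 0, g$m))
    out <- rbind(
      matrix(g$tau[, , 1], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[1],
      matrix(g$tau[, , 2], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[1],
      matrix(g$tau[, , 3], g$nn, g$m)[r, , drop = FALSE] / .dyn_scales[2])
    if (with_moments && !is.null(g$Mmus)) {
      out <- rbind(out, do.call(rbind, lapply(model$mdofs, function(ci)
        (matrix(g$tau[, , ci], g$nn, g$m)[r, , drop = FALSE] -
           g$Mmus[[ci]][r, , drop = FALSE]) / 100)))
    }
    out
  }
}

# tracking residual of a coordinate against data at node times
track_coord_fn <- function(model, opts, data_q, weights) {
  function(traj) {
    out <- NULL
    qw <- NULL
    for (i in seq_along(weights)) {
      if (weights[i] == 0) next
      if (is.null(qw)) qw <- sqrt(node_quad_w(traj))
      ni <- traj$node_idx
      out <- rbind(out, sqrt(weights[i]) * qw *
                     (traj$q[[i]][ni, , drop = FALSE] - data_q[, i]))
    }
    out
  }
}

# tracking residual of per-foot ground reactions (fx, fy) against data
track_grf_fn <- function(model, opts, data_grf, weight) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$node_rows
    qw <- sqrt(node_quad_w(traj))
    sub <- function(M) M[r, , drop = FALSE]
    sqrt(weight) * rbind(qw * (sub(g$grf$r$fx) - data_grf$r_fx),
                         qw * (sub(g$grf$r$fy) - data_grf$r_fy),
                         qw * (sub(g$grf$l$fx) - data_grf$l_fx),
                         qw * (sub(g$grf$l$fy) - data_grf$l_fy))
  }
}

# tracking residual of required joint moments against inverse-dynamics data
track_moment_fn <- function(model, opts, data_mom, weight, hip_factor = 2) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$node_rows
    qw <- sqrt(node_quad_w(traj))
    out <- NULL
    for (j in seq_along(model$mdofs)) {
      ci <- model$mdofs[j]
      wj <- weight * if (grepl("hip", model$skel$coords[ci])) hip_factor else 1
      out <- rbind(out, sqrt(wj) * qw *
                     (matrix(g$tau[, , ci], g$nn, g$m)[r, , drop = FALSE] -
                        data_mom[, j]))
    }
    out
  }
}

# integrated-squared jerk regularization over all coordinates
jerk_cost_fn <- function(scale = 1000) {
  function(traj) {
    do.call(rbind, lapply(traj$jerk, function(J) sqrt(traj$qw) * J / scale))
  }
}

# jerk roughness: node-to-node jerk differences. Damps the sawtooth jerk
# modes that would otherwise ring between collocation nodes (where the path
# constraints are not imposed).
jerk_smooth_fn <- function(scale = 1000) {
  function(traj) {
    ni <- traj$node_idx
    do.call(rbind, lapply(traj$jerk, function(J) {
      Jn <- J[ni, , drop = FALSE]
      (Jn[-1, , drop = FALSE] - Jn[-nrow(Jn), , drop = FALSE]) / scale
    }))
  }
}

# toe joints are torque-actuated; keep those torques small
toe_torque_fn <- function(model, opts, scale = 20) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    r <- g$node_rows
    qw <- sqrt(node_quad_w(traj))
    do.call(rbind, lapply(model$toe_dofs, function(ci)
      qw * matrix(g$tau[, , ci], g$nn, g$m)[r, , drop = FALSE] / scale))
  }
}

# total anterior-posterior impulse over the cycle (both legs): a periodic
# solution of the translating model must have zero net fore-aft impulse, so
# this is imposed as an equality constraint, pinning the discretized
# momentum balance exactly
net_ap_impulse_fn <- function(model, opts) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    w <- if (length(g$mid_rows)) traj$qw[g$rows] else node_quad_w(traj)
    matrix(colSums((g$grf$l$fx + g$grf$r$fx) * w), 1)
  }
}

# node-to-node slope of the synergy-activation controls: a weak rate
# regularizer keeping neural drives within physiological rise/decay rates
control_slope_fn <- function(n_u, scale = 0.3) {
  function(traj) {
    ni <- traj$node_idx
    do.call(rbind, lapply(seq_len(n_u), function(k) {
      Un <- traj$u[[k]][ni, , drop = FALSE]
      (Un[-1, , drop = FALSE] - Un[-nrow(Un), , drop = FALSE]) / scale
    }))
  }
}

# signed difference in anterior-posterior force impulse between the legs
# (Simpson quadrature when the pipeline is evaluated at midpoints too)
ap_impulse_diff_fn <- function(model, opts) {
  function(traj) {
    g <- gait_pipeline(model, traj, opts)
    w <- if (length(g$mid_rows)) traj$qw[g$rows] else node_quad_w(traj)
    matrix(colSums(g$grf$l$fx * w) - colSums(g$grf$r$fx * w), 1)
  }
}

# add standard periodicity pairs: q (pelvis_x shifted by stride), qd, qdd,
# and synergy controls
add_gait_periodicity <- function(ocp, model, n_u = 0) {
  stride <- model$belt_speed * model$t_end
  for (i in seq_along(model$skel$coords)) {
    nm <- model$skel$coords[i]
    shift <- if (nm == "pelvis_x") stride else 0
    local({
      ii <- i
      ocp <<- add_periodicity(ocp, paste0("q.", nm),
                              function(tr) tr$q[[ii]], shift = shift, scale = 0.05)
      ocp <<- add_periodicity(ocp, paste0("qd.", nm),
                              function(tr) tr$qd[[ii]], scale = 0.5)
      ocp <<- add_periodicity(ocp, paste0("qdd.", nm),
                              function(tr) tr$qdd[[ii]], scale = 10)
    })
  }
  for (k in seq_len(n_u)) {
    local({
      kk <- k
      ocp <<- add_periodicity(ocp, paste0("u.", kk),
                              function(tr) tr$u[[kk]], scale = 0.2)
    })
  }
  ocp
}

# default variable scales for gait problems
gait_scales <- function() {
  list(q = c(0.5, 0.2, 0.2, rep(0.5, 8)),
       qd = c(1, 1, 1, rep(4, 8)),
       qdd = c(10, 10, 10, rep(40, 8)),
       jerk = c(200, 200, 200, rep(800, 8)))
}

# initial variable vector from target coordinate series sampled at the
# collocation points (matrix np x n_q), plus controls and statics
gait_initial_guess <- function(nlp, q_target, u_target = NULL, s0 = NULL) {
  nlp$make_guess(q_target, u_target = u_target, s0 = s0)
}

# warm-start vector for `nlp` from a previous solution's trajectory,
# optionally overriding controls/statics
warm_start_from <- function(nlp, solution, s0 = NULL, u_target = NULL) {
  tr <- solution$traj
  q_t <- sapply(tr$q, function(M) M[, 1])
  if (is.null(u_target) && length(tr$u) && nlp$ocp$n_u == length(tr$u)) {
    u_target <- sapply(tr$u, function(M) M[tr$node_idx, 1])
  }
  nlp$make_guess(q_t, u_target = u_target, s0 = s0)
}

#' Net joint moments generated by the muscles
#'
#' Sums moment-arm-weighted rigid-tendon Hill forces over all muscles for
#' each muscle-actuated degree of freedom (toes are torque-actuated and
#' excluded).
#'
#' @param model a `gait_model`.
#' @param q,qdot coordinate and rate vectors (length 11).
#' @param activations named (or model-ordered) activation vector in `[0,1]`.
#' @return named vector of moments (N m) over hip/knee/ankle of both legs.
#' @export
joint_moments_from_muscles <- function(model, q, qdot, activations) {
  if (any(activations < 0 - 1e-12) || any(activations > 1 + 1e-12))
    stop_gaitfes("activations must be in [0, 1]")
  if (!is.null(names(activations)))
    activations <- activations[model$muscle_names]
  mom <- numeric(length(model$skel$coords))
  for (mi in seq_along(model$muscle_names)) {
    nm <- model$muscle_names[mi]
    mk <- muscle_tendon_kinematics(q, qdot, model$surrogates[[nm]])
    Fm <- muscle_force(activations[mi], mk$lmt, mk$vmt,
                       model$muscles$params[[nm]])
    for (j in seq_along(mk$arms)) {
      ci <- model$surrogates[[nm]]$coord_idx[j]
      mom[ci] <- mom[ci] + mk$arms[j] * Fm
    }
  }
  out <- mom[model$mdofs]
  names(out) <- model$skel$coords[model$mdofs]
  out
}

#' Time-series outputs of a gait solution at the mesh nodes
#'
#' @param model a `gait_model`. @param solution an `ocp_solution`.
#' @param opts pipeline options used when the problem was built.
#' @return list with `t`, `q` (nn x 11), per-foot GRFs, joint moments,
#'   muscle activations (if muscle-driven), and synergy controls.
#' @export
gait_outputs <- function(model, solution, opts) {
  traj <- solution$traj
  traj$cache <- new.env(parent = emptyenv())
  # evaluate at every collocation point (nodes + midpoints) so integral
  # metrics can use Simpson quadrature
  traj$node_idx <- seq_len(traj$np)
  g <- gait_pipeline(model, traj, opts)
  q <- sapply(traj$q, function(M) M[, 1])
  colnames(q) <- model$skel$coords
  grf_out <- lapply(c(r = "r", l = "l"), function(sd) {
    fx <- g$grf[[sd]]$fx[, 1]; fy <- g$grf[[sd]]$fy[, 1]
    list(fx = fx, fy = fy, mz = g$grf[[sd]]$mz[, 1],
         cop = ifelse(fy > 1, g$grf[[sd]]$x_weighted[, 1] / fy, NA_real_))
  })
  out <- list(t = traj$t, qw = traj$qw, q = q, grf = grf_out,
              tau = apply(g$tau, 3, function(M) M[, 1]))
  if (!is.null(g$act)) {
    act <- sapply(g$act, function(M) M[, 1])
    colnames(act) <- model$muscle_names
    out$activations <- act
    out$C <- sapply(seq_len(2 * model$n_syn), function(k) traj$u[[k]][, 1])
    if (!is.null(opts$stim)) {
      out$a_stim <- lapply(g$a_stim, function(M) if (is.null(M)) NULL else M[, 1])
    }
  }
  out
}
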