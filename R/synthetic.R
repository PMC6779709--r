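# Virtual-patient generator: ground-truth planar models with an imposed
# paretic plantarflexor deficit, dynamically consistent reference gait built
# by a tracking optimal control problem on the true model, and synthesis of
# noisy measurement sets (markers, ground reactions, EMG envelopes) with all
# ground truth retained for recovery testing.

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# Ankle-point and foot-pitch trajectory of one leg over its own cycle
# (heel strike at s = 0), in the ground frame. Flat-foot stance with the
# ankle pinned (zero slip), heel rise pivoting about the metatarsals, and a
# swing that lands flat with zero velocity (ground-speed matched). `X0` is
# the stance ankle x of the current cycle.
leg_foot_track <- function(s, X0, stride, skel, rho_max = 20 * pi / 180,
                           d_pen = 0.005, flat_end = 0.42, toe_off = 0.58,
                           clearance = 0.05) {
  ax <- skel$mtp_x             # ankle-to-MTP distance in foot frame
  ay <- -skel$foot_sole_y      # ankle height above sole
  # penetration bell over stance
  d <- d_pen * smoothstep(s / 0.08) * (1 - smoothstep((s - 0.50) / 0.08))
  rho <- rho_max * smoothstep((s - flat_end) / (toe_off - flat_end))
  in_stance <- s < toe_off
  # heel-rise geometry: MTP fixed at (X0 + ax, -d), foot pitch -rho
  hr_x <- X0 + ax - ax * cos(rho) + ay * sin(rho)
  hr_y <- -d + ax * sin(rho) + ay * cos(rho)
  x_st <- ifelse(s < flat_end, X0, hr_x)
  y_st <- ifelse(s < flat_end, ay - d, hr_y)
  # swing: zero-velocity endpoints (smoothstep has zero end slopes)
  u <- (s - toe_off) / (1 - toe_off)
  x0_sw <- X0 + ax - ax * cos(rho_max) + ay * sin(rho_max)
  y0_sw <- ax * sin(rho_max) + ay * cos(rho_max)
  x_sw <- x0_sw + (X0 + stride - x0_sw) * smoothstep(u)
  y_sw <- y0_sw + (ay - y0_sw) * smoothstep(u) + clearance * sin(pi * pmin(pmax(u, 0), 1))^2
  rho_sw <- rho_max * (1 - smoothstep(u / 0.5))
  list(x = ifelse(in_stance, x_st, x_sw),
       y = ifelse(in_stance, y_st, y_sw),
       pitch = ifelse(in_stance, -rho, -rho_sw),
       toe = ifelse(in_stance, rho, rho_sw))
}

# closed-form planar two-link inverse kinematics of one leg
leg_ik <- function(hip_x, hip_y, ankle_x, ankle_y, pitch, toe_rel, Lt, Ls) {
  dx <- ankle_x - hip_x; dy <- ankle_y - hip_y
  D <- pmin(sqrt(dx^2 + dy^2), (Lt + Ls) * 0.9995)
  gam <- acos(pmin(pmax((Lt^2 + Ls^2 - D^2) / (2 * Lt * Ls), -1), 1))
  knee <- pi - gam
  beta <- atan2(dx, -dy)
  alpha <- acos(pmin(pmax((Lt^2 + D^2 - Ls^2) / (2 * Lt * D), -1), 1))
  hip <- beta + alpha
  ankle <- pitch - (hip - knee)
  list(hip = hip, knee = knee, ankle = ankle, toe = toe_rel)
}

#' Nominal gait template for the virtual patient
#'
#' Kinematically ground-consistent walking built from foot trajectories:
#' during stance the flat foot is pinned to the ground with a small
#' penetration bell (engaging the compliant contact), late stance pivots the
#' heel about the metatarsal joint, and swing lands flat with zero foot
#' velocity. Joint angles follow by closed-form two-link inverse kinematics;
#' the left leg is the right leg shifted by half a cycle.
#'
#' @param skel a `planar_skeleton`.
#' @param t times at which to evaluate (s).
#' @param t_end cycle duration (s).
#' @param belt_speed progression speed (m/s).
#' @param d_pen stance penetration depth (m).
#' @param step_shift step-length asymmetry (m): the paretic (right) foot
#'   lands this much further forward, the non-paretic foot closer — the
#'   longer-paretic-step pattern typical of hemiparetic gait.
#' @return matrix (length(t) x 11) of coordinates (rad, m).
#' @export
gait_template <- function(skel, t, t_end, belt_speed, d_pen = 0.005,
                          step_shift = 0.03) {
  s <- t / t_end
  stride <- belt_speed * t_end
  Lt <- 0.42; Ls <- 0.43
  n <- length(s)
  q <- matrix(0, n, length(skel$coords))
  colnames(q) <- skel$coords
  q[, "pelvis_x"] <- belt_speed * t
  hip_off <- skel$segments$thigh_r$joint_in_parent   # hip joint in pelvis frame
  # pelvis height: bob twice per stride, lowest near double support
  pel_y <- 0.970 + 0.008 * cos(4 * pi * (s - 0.30))
  q[, "pelvis_y"] <- pel_y
  hip_x <- q[, "pelvis_x"] + hip_off[1]
  hip_y <- pel_y + hip_off[2]
  for (side in c("r", "l")) {
    off <- if (side == "r") 0 else 0.5
    s_leg <- (s - off) %% 1
    # stance ankle x for the cycle this sample's stance belongs to
    X0 <- belt_speed * t_end * (s - s_leg) + 0.25 * stride +
      if (side == "r") step_shift else -step_shift
    ft <- leg_foot_track(s_leg, X0, stride, skel, d_pen = d_pen)
    ik <- leg_ik(hip_x, hip_y, ft$x, ft$y, ft$pitch, ft$toe, Lt, Ls)
    q[, paste0("hip_", side)] <- ik$hip
    q[, paste0("knee_", side)] <- ik$knee
    q[, paste0("ankle_", side)] <- ik$ankle
    q[, paste0("toe_", side)] <- ik$toe
  }
  q
}

# ground-truth synergy structure: 3 synergies per leg over the 9-muscle
# order (iliopsoas, glutei, hamstrings, rectus femoris, vasti, bifemsh,
# gastrocnemius, soleus, tibialis anterior)
# Five synergies per leg with well-decoupled dominant muscles (knee
# extension, push-off, hip flexion/swing, flexor mass at strike, hip
# extension) so the positive span of the synergy-to-moment map covers the
# moment demands of walking. Muscle row order: iliopsoas, glutei,
# hamstrings, rectus femoris, vasti, bifemsh, gastrocnemius, soleus,
# tibialis anterior.
.true_W_leg <- function() {
  W <- cbind(
    knee_ext = c(0.00, 0.30, 0.00, 0.10, 0.95, 0.00, 0.00, 0.10, 0.00),
    pushoff  = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.05, 0.35, 0.95, 0.00),
    swing    = c(0.95, 0.00, 0.00, 0.10, 0.00, 0.20, 0.00, 0.00, 0.30),
    strike   = c(0.00, 0.25, 0.70, 0.00, 0.00, 0.40, 0.10, 0.00, 0.45),
    hip_ext  = c(0.00, 0.90, 0.30, 0.00, 0.10, 0.00, 0.00, 0.00, 0.00))
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

gauss_bump <- function(s, center, width, amp) {
  d <- abs((s - center) %% 1)
  d <- pmin(d, 1 - d)
  amp * exp(-0.5 * (d / width)^2)
}

template_C_leg <- function(s) {
  rbind(0.05 + gauss_bump(s, 0.08, 0.10, 0.55),
        0.02 + gauss_bump(s, 0.45, 0.09, 0.70),
        0.02 + gauss_bump(s, 0.72, 0.11, 0.55),
        0.02 + gauss_bump(s, 0.97, 0.07, 0.40),
        0.03 + gauss_bump(s, 0.10, 0.12, 0.45))
}

#' Construct a virtual patient with known ground truth
#'
#' Deterministic given the seed. The paretic (right) leg's plantarflexor
#' (soleus and gastrocnemius) synergy weights are scaled by the deficit
#' factor, emulating reduced paretic push-off drive.
#'
#' @param config list; recognized entries (with defaults):
#'   `deficit` (0.4), `t_end` (1.2 s), `belt_speed` (0.6 m/s),
#'   `marker_sd` (0.003 m), `grf_sd` (2 N), `emg_sd` (0.05 multiplicative),
#'   `missing` (c("iliopsoas", "bifemsh")), `N` (mesh intervals, 14).
#' @param seed master seed (integer).
#' @return `virtual_patient`: ground-truth `gait_model` (`$model`), true
#'   synergy template, marker definitions, noise spec, and seed.
#' @export
make_virtual_patient <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(deficit = 0.4, t_end = 1.2, belt_speed = 0.6,
                                marker_sd = 0.003, grf_sd = 2, emg_sd = 0.05,
                                missing = c("iliopsoas", "bifemsh"), N = 14),
                           config)
  if (cfg$deficit <= 0 || cfg$deficit > 1)
    stop_gaitfes("deficit factor must be in (0, 1]")
  skel <- default_skeleton()
  mus <- default_muscles(skel)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  # per-muscle "physiological" truth, varied but reproducible
  for (nm in names(mus$params)) {
    mus$params[[nm]]$emg_scale <- round(stats::runif(1, 0.60, 0.95), 3)
    mus$params[[nm]]$emd <- round(stats::runif(1, 0.025, 0.055), 4)
    mus$params[[nm]]$shape <- round(stats::runif(1, 0.5, 2.0), 3)
  }
  sur <- build_surrogates(skel, mus)
  cp <- contact_params(stiffness = 1e9, damping = 1.0, mu_d = 0.8,
                       mu_v = 0.5, belt_speed = 0)
  elems <- default_contact_elements(skel)
  W0 <- .true_W_leg()
  Wr <- W0; Wl <- W0
  rownames(Wr) <- paste0(.muscle_base$base, "_r")
  rownames(Wl) <- paste0(.muscle_base$base, "_l")
  Wr[c(7, 8), ] <- Wr[c(7, 8), ] * cfg$deficit   # gastrocnemius, soleus rows
  W <- list(r = Wr, l = Wl)
  status <- ifelse(sub("_[rl]$", "", names(mus$params)) %in% cfg$missing,
                   "predicted", "measured")
  names(status) <- names(mus$params)
  model <- gait_model(skel, mus, sur, cp, elems, W = W, t_end = cfg$t_end,
                      belt_speed = cfg$belt_speed, n_syn = ncol(W0),
                      emg_status = status)
  markers <- list(
    pelvis = list(PEL1 = c(0.08, 0.10), PEL2 = c(-0.10, 0.08), PEL3 = c(0.00, -0.02)),
    thigh = list(THI1 = c(0.04, -0.15), THI2 = c(-0.03, -0.30)),
    shank = list(SHA1 = c(0.04, -0.12), SHA2 = c(-0.03, -0.30)),
    foot = list(ANK = c(0.02, 0.01), HEE = c(-0.05, -0.06), MT = c(0.12, -0.07)),
    toe = list(TOE = c(0.05, -0.005), TO2 = c(0.015, 0.012)))
  structure(list(model = model, config = cfg, seed = seed, markers = markers,
                 deficit = cfg$deficit),
            class = "virtual_patient")
}

#' Perturbed initial-guess model for personalization recovery studies
#'
#' Takes the virtual patient's ground-truth model and displaces everything a
#' calibration is expected to recover: joint centres by ~1.5 cm, optimal
#' fiber lengths by +/-10%, tendon slack lengths by -/+5% (alternating so
#' the perturbations do not cancel), EMG scales/delays/shapes to generic
#' flat defaults, contact stiffness doubled and friction/damping moved off
#' their true values. Synergy vectors are dropped entirely (stage 4
#' recalibrates them).
#'
#' @param patient a `virtual_patient`.
#' @param seed controls the perturbation signs.
#' @return a `gait_model` suitable as `model_init` for [personalize()].
#' @export
perturbed_initial_model <- function(patient, seed = 1) {
  model <- patient$model
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed + 500L)
  for (sg in c("thigh_r", "shank_r", "foot_r", "thigh_l", "shank_l", "foot_l")) {
    model$skel$segments[[sg]]$joint_in_parent <-
      model$skel$segments[[sg]]$joint_in_parent +
      stats::runif(2, -0.015, 0.015)
  }
  sgn <- 1
  for (nm in names(model$muscles$params)) {
    p <- model$muscles$params[[nm]]
    p$l_opt <- p$l_opt * (1 + sgn * 0.10)
    p$l_ts <- p$l_ts * (1 - sgn * 0.05)
    p$emg_scale <- 0.75
    p$emd <- 0.04
    p$shape <- 1.0
    p$tau_act <- 0.015
    p$tau_deact <- 0.060
    model$muscles$params[[nm]] <- p
    sgn <- -sgn
  }
  model$contact$stiffness <- model$contact$stiffness * 2
  model$contact$damping <- 0.5
  model$contact$mu_d <- 0.6
  model$contact$mu_v <- 0.8
  model$W <- NULL
  model
}

#' Passive joint-moment reference from the ground-truth model
#'
#' Evaluates the true model's passive (zero-activation) hip/knee/ankle
#' moments at a grid of poses spanning the joint ranges — the synthetic
#' stand-in for published passive-moment tables.
#'
#' @param patient a `virtual_patient`.
#' @param n poses per leg.
#' @return list with entries `r` and `l`: list(poses = n x 11, moments = n x 3).
#' @export
passive_reference <- function(patient, n = 24) {
  model <- patient$model
  rngs <- default_joint_ranges()
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(31L)
  out <- list()
  for (side in c("r", "l")) {
    dofs <- match(paste0(c("hip_", "knee_", "ankle_"), side), model$skel$coords)
    # corners of the joint-range box (where passive forces engage and pin
    # the fiber/tendon length split) plus random interior poses
    corners <- as.matrix(expand.grid(lapply(c("hip", "knee", "ankle"),
      function(j) rngs[[j]] + c(0.03, -0.03))))
    n_int <- max(n - nrow(corners), 4)
    interior <- sapply(1:3, function(j) {
      r <- rngs[[c("hip", "knee", "ankle")[j]]]
      stats::runif(n_int, r[1] + 0.05, r[2] - 0.05)
    })
    grid3 <- rbind(corners, interior)
    poses <- matrix(0, nrow(grid3), 11)
    for (j in 1:3) poses[, dofs[j]] <- grid3[, j]
    mom <- matrix(0, n, 3)
    for (mi in muscles_of_side(model, side)) {
      nm <- model$muscle_names[mi]
      geom <- model$surrogates[[nm]]
      qlist <- lapply(geom$coord_idx, function(ci) matrix(poses[, ci], n, 1))
      ev <- surrogate_eval_batched(geom, qlist)
      Fp <- hill_force_batched(0, ev$len, 0, model$muscles$params[[nm]])
      for (j in seq_along(geom$coord_idx)) {
        d <- match(geom$coord_idx[j], dofs)
        if (!is.na(d)) mom[, d] <- mom[, d] + ev$arms[[j]][, 1] * Fp[, 1]
      }
    }
    out[[side]] <- list(poses = poses, moments = mom)
  }
  out
}

#' Generate the dynamically consistent reference gait of a virtual patient
#'
#' Solves a tracking optimal control problem on the ground-truth model:
#' synergy-activation controls (true synergy vectors fixed) and joint-jerk
#' controls track the nominal joint-angle template under full dynamics,
#' contact, and periodicity constraints. A deficit patient exhibits
#' anterior-posterior impulse asymmetry; the generator asserts this.
#'
#' @param patient a `virtual_patient`.
#' @param N mesh intervals (defaults to the patient's config).
#' @param assert check the deficit signature (default TRUE).
#' @return list with the `ocp_solution` (`$solution`), node outputs
#'   (`$outputs`), pipeline `opts`, and AP impulse summary (`$impulses`).
#' @export
generate_reference_gait <- function(patient, N = patient$config$N, assert = TRUE,
                                    verbose = FALSE, max_outer = 12,
                                    max_inner = 40) {
  model <- patient$model
  n_u <- 2 * model$n_syn
  opts <- list(muscle_driven = TRUE, contact_source = "model", W_source = "model",
               eval_all = TRUE)
  sc <- gait_scales()
  ocp <- ocp_definition(n_q = 11, n_u = n_u, N = N, t_end = model$t_end,
                        scale_q = sc$q, scale_qd = sc$qd, scale_qdd = sc$qdd,
                        scale_jerk = sc$jerk, scale_u = 0.5)
  nlp0 <- transcribe(ocp)   # for mesh times
  tcol <- nlp0$mesh$t
  q_tmpl <- gait_template(model$skel, tcol, model$t_end, model$belt_speed)
  # drop the pelvis until the template's cycle-average vertical ground
  # reaction supports body weight (good vertical-equilibrium start)
  bw <- sum(vapply(model$skel$segments, `[[`, 0, "mass")) * model$skel$gravity
  mean_fy <- function(dy) {
    qx <- q_tmpl; qx[, 2] <- qx[, 2] + dy
    fk <- fk_batched(model$skel, array(qx, c(nrow(qx), 1, 11)))
    fr <- foot_contact_batched(model$skel, fk, model$elements, model$contact, "r")
    fl <- foot_contact_batched(model$skel, fk, model$elements, model$contact, "l")
    mean(fr$fy + fl$fy)
  }
  dy_grid <- seq(-0.012, 0.004, by = 5e-4)
  fy_grid <- vapply(dy_grid, mean_fy, 0)
  q_tmpl[, 2] <- q_tmpl[, 2] + dy_grid[which.min(abs(fy_grid - bw))]
  tn <- tcol[seq(1, length(tcol), 2)]
  C_tmpl <- cbind(t(template_C_leg(tn / model$t_end)),
                  t(template_C_leg(tn / model$t_end + 0.5)))
  w_track <- c(5, 200, 200, rep(30, 8))
  ocp <- add_cost(ocp, "track_q", 1,
                  track_coord_fn(model, opts, q_tmpl[seq(1, nrow(q_tmpl), 2), ],
                                 w_track))
  C_nodes_tmpl <- C_tmpl
  ocp <- add_cost(ocp, "reg_C", 0.2, function(tr) {
    qw <- sqrt(node_quad_w(tr))
    do.call(rbind, lapply(seq_len(n_u), function(k)
      qw * (tr$u[[k]][tr$node_idx, , drop = FALSE] - C_nodes_tmpl[, k])))
  })
  ocp <- add_cost(ocp, "jerk", 0.02, jerk_cost_fn())
  ocp <- add_cost(ocp, "jerk_smooth", 0.05, jerk_smooth_fn())
  ocp <- add_cost(ocp, "mid_dynamics", 0.3, mid_dynamics_fn(model, opts))
  ocp <- add_cost(ocp, "toe_torque", 0.5, toe_torque_fn(model, opts))
  ocp <- add_cost(ocp, "reg_C_slope", 0.1, control_slope_fn(n_u))
  ocp <- add_path_constraint(ocp, "pelvis_dynamics", pelvis_residual_fn(model, opts))
  ocp <- add_path_constraint(ocp, "pelvis_x_mid", pelvis_x_mid_fn(model, opts))
  ocp <- add_path_constraint(ocp, "moment_match", moment_match_fn(model, opts))
  ocp <- add_gait_periodicity(ocp, model, n_u = n_u)
  ocp <- set_bounds(ocp, "u", 0, 1.5)
  nlp <- transcribe(ocp)
  # initial guess: template kinematics + template synergy activations
  z0 <- gait_initial_guess(nlp, q_tmpl, u_target = C_tmpl)
  sol <- solve_ocp(nlp, z0, tol = 1e-6, max_outer = max_outer,
                   max_inner = max_inner, verbose = verbose)
  out <- gait_outputs(model, sol, opts)
  w <- out$qw
  imp <- list(r = sum(out$grf$r$fx * w), l = sum(out$grf$l$fx * w),
              r_prop = sum(pmax(out$grf$r$fx, 0) * w),
              l_prop = sum(pmax(out$grf$l$fx, 0) * w))
  imp$diff <- abs(imp$l - imp$r)
  if (assert && patient$deficit < 1) {
    if (imp$diff <= 1)
      warning("deficit patient shows AP impulse asymmetry of only ",
              signif(imp$diff, 3), " N s")
    if (max(out$grf$r$fx) >= max(out$grf$l$fx))
      warning("paretic propulsive peak is not below non-paretic peak")
  }
  list(solution = sol, outputs = out, opts = opts, impulses = imp,
       template_q = q_tmpl, template_C = C_tmpl, nlp = nlp)
}

#' Synthesize a noisy measured gait trial from a reference gait
#'
#' Markers are segment-attached points plus Gaussian noise; ground reactions
#' get additive Gaussian noise; EMG envelopes are derived from the true
#' activations by inverting the activation nonlinearity and activation
#' dynamics, removing the electromechanical delay, and dividing by the true
#' EMG scale factor, then applying multiplicative noise. Channels for
#' muscles with predicted status are withheld.
#'
#' @param gait output of [generate_reference_gait()].
#' @param patient the `virtual_patient`.
#' @param seed noise seed.
#' @param n_samples samples over the cycle (default 101).
#' @param noise optional override of the patient's noise spec (set all zero
#'   for a noiseless trial).
#' @return `gait_trial`: `t`, `markers` (named list of n x 2 matrices),
#'   `grf` (`r`/`l` with `fx`, `fy`, `mz`), `emg` (n x channels), `events`,
#'   `belt_speed`, `t_end`, plus `$truth` (activations, excitation-inversion
#'   residual).
#' @export
synthesize_measurements <- function(gait, patient, seed = 1, n_samples = 101,
                                    noise = NULL) {
  model <- patient$model
  cfg <- patient$config
  if (!is.null(noise)) cfg[names(noise)] <- noise
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed + 1000L)
  tt <- seq(0, model$t_end, length.out = n_samples)
  traj <- gait$solution$traj
  q_fine <- sapply(seq_len(11), function(i)
    interp_periodic(traj$t, traj$q[[i]][, 1], tt, model$t_end))
  # pelvis_x is periodic only modulo the stride; interpolate its deviation
  stride <- model$belt_speed * model$t_end
  devx <- traj$q[[1]][, 1] - model$belt_speed * traj$t
  q_fine[, 1] <- interp_periodic(traj$t, devx, tt, model$t_end) +
    model$belt_speed * tt
  qd_fine <- sapply(seq_len(11), function(i)
    interp_periodic(traj$t, traj$qd[[i]][, 1], tt, model$t_end))
  fk <- fk_batched(model$skel, array(q_fine, c(n_samples, 1, 11)))
  markers <- list()
  for (seg_base in names(patient$markers)) {
    for (side in if (seg_base == "pelvis") "" else c("r", "l")) {
      seg <- if (seg_base == "pelvis") "pelvis" else paste0(seg_base, "_", side)
      pre <- if (seg_base == "pelvis") "" else if (side == "r") "P_" else "N_"
      for (mn in names(patient$markers[[seg_base]])) {
        p <- patient$markers[[seg_base]][[mn]]
        pp <- rot2(fk[[seg]]$th, p[1], p[2])
        xy <- cbind(fk[[seg]]$ox[, 1] + pp$x[, 1], fk[[seg]]$oy[, 1] + pp$y[, 1])
        xy <- xy + matrix(stats::rnorm(2 * n_samples, 0, cfg$marker_sd), ncol = 2)
        markers[[paste0(pre, mn)]] <- xy
      }
    }
  }
  # ground reactions at sample times
  out <- gait$outputs
  grf <- list()
  for (side in c("r", "l")) {
    cop <- out$grf[[side]]$cop
    cop_dev <- ifelse(is.na(cop), NA, cop - out$q[, 1])   # CoP relative pelvis
    cop_i <- stats::approx(out$t, cop_dev, xout = tt, rule = 2)$y +
      interp_trend(out$t, out$q[, 1], tt, model$t_end, trend = model$belt_speed)
    grf[[side]] <- list(
      fx = interp_periodic(out$t, out$grf[[side]]$fx, tt, model$t_end) +
        stats::rnorm(n_samples, 0, cfg$grf_sd),
      fy = interp_periodic(out$t, out$grf[[side]]$fy, tt, model$t_end) +
        stats::rnorm(n_samples, 0, cfg$grf_sd),
      mz = rep(0, n_samples),
      cop = cop_i)
    grf[[side]]$cop[grf[[side]]$fy <= 5] <- NA
  }
  # EMG envelopes by inverse pipeline from true activations
  act_fine <- sapply(seq_len(ncol(out$activations)), function(j)
    pmin(pmax(interp_periodic(out$t, out$activations[, j], tt, model$t_end), 0), 1))
  colnames(act_fine) <- model$muscle_names
  dt <- tt[2] - tt[1]
  emg <- NULL; emg_names <- character(0)
  inv_res <- 0
  for (mi in seq_along(model$muscle_names)) {
    nm <- model$muscle_names[mi]
    if (model$emg_status[nm] != "measured") next
    p <- model$muscles$params[[nm]]
    u <- invert_activation_dynamics(act_fine[, mi], p, dt)
    # check forward reconstruction quality (reported, not hidden)
    a_chk <- activation_dynamics(u, p, dt, a0 = u[1])
    inv_res <- max(inv_res, max(abs(a_chk - act_fine[, mi])))
    env <- delay_periodic(u, tt, -p$emd, model$t_end) / p$emg_scale
    env <- pmax(env * (1 + stats::rnorm(n_samples, 0, cfg$emg_sd)), 0)
    emg <- cbind(emg, env); emg_names <- c(emg_names, nm)
  }
  colnames(emg) <- emg_names
  # gait events from vertical GRF threshold (paretic heel strike = 0%)
  events <- detect_gait_events(tt, grf, model$t_end)
  structure(list(t = tt, markers = markers, grf = grf, emg = emg,
                 events = events, belt_speed = model$belt_speed,
                 t_end = model$t_end,
                 truth = list(activations = act_fine, q = q_fine, qd = qd_fine,
                              inversion_residual = inv_res)),
            class = "gait_trial")
}

#' Detect heel-strike / toe-off events from vertical GRF
#' @param t time vector. @param grf per-foot GRFs. @param t_end cycle (s).
#' @return list of event times in % gait cycle.
#' @export
detect_gait_events <- function(t, grf, t_end, threshold = 20) {
  ev <- list()
  for (side in c("r", "l")) {
    on <- grf[[side]]$fy > threshold
    prev <- c(on[length(on)], on[-length(on)])    # periodic predecessor
    trans_on <- which(!prev & on)
    trans_off <- which(prev & !on)
    ev[[paste0("heel_strike_", side)]] <- if (length(trans_on))
      100 * t[trans_on[1]] / t_end else 0
    ev[[paste0("toe_off_", side)]] <- if (length(trans_off))
      100 * t[trans_off[1]] / t_end else 50
  }
  ev
}

#' Miniature deterministic fixture for unit tests
#'
#' A single-leg toy: right hip-knee-ankle chain poses on a 20-point grid with
#' two muscles (soleus, tibialis anterior), activations varying over the
#' grid, and the ankle moment each combination produces. The expected-moment
#' table is computed from the geometric path model directly (independent of
#' the surrogate route normally used).
#'
#' @return list with `poses` (20 x 11), `muscles`, `activations` (20 x 2),
#'   `expected_ankle_moment` (N m), and the model pieces used.
#' @export
fixture_small <- function() {
  skel <- default_skeleton()
  mus <- default_muscles(skel)
  keep <- c("soleus_r", "tibialis_anterior_r")
  s <- seq(0, 1, length.out = 20)
  poses <- matrix(0, 20, 11)
  colnames(poses) <- skel$coords
  poses[, "hip_r"] <- 0.3 * sin(2 * pi * s)
  poses[, "knee_r"] <- 0.4 + 0.3 * cos(2 * pi * s)
  poses[, "ankle_r"] <- 0.3 * sin(4 * pi * s) - 0.1
  act <- cbind(soleus_r = 0.5 + 0.4 * sin(2 * pi * s)^2,
               tibialis_anterior_r = 0.3 + 0.3 * cos(2 * pi * s)^2)
  mom <- numeric(20)
  for (k in 1:20) {
    for (j in seq_along(keep)) {
      nm <- keep[j]
      lmt <- path_length(skel, mus$paths[[nm]], poses[k, ])
      arm <- path_moment_arms(skel, mus$paths[[nm]], poses[k, ])[["ankle_r"]]
      F <- muscle_force(act[k, j], lmt, 0, mus$params[[nm]])
      mom[k] <- mom[k] + arm * F
    }
  }
  list(poses = poses, muscles = keep, activations = act,
       expected_ankle_moment = mom, skel = skel, mus = mus)
}
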