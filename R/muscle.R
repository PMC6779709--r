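# Hill-type muscle model with rigid tendon, activation dynamics, and the
# default muscle set of the planar model (9 muscles per leg).
#
# Force-length/velocity/passive curves are smooth (tanh/exp/log) forms from
# the rigid-tendon EMG-driven literature, normalized so that
# F(a=1, l_fiber=l_opt, v=0) = F_max and f_pas(1) = 0 exactly; smoothness is
# required because the optimal-control solver differentiates through them.

# --- normalized force curves ------------------------------------------------

.fl_b <- matrix(c(0.8145, 1.0550, 0.1624, 0.0633,
                  0.4330, 0.7168, -0.0299, 0.2004,
                  0.1000, 1.0000, 0.3536, 0.0000), 4, 3)

fl_active_raw <- function(l) {
  out <- 0
  for (k in 1:3) {
    b <- .fl_b[, k]
    out <- out + b[1] * exp(-0.5 * (l - b[2])^2 / (b[3] + b[4] * l)^2)
  }
  out
}
.fl_norm <- NULL  # set on load

fv_raw <- function(v) {
  d1 <- -0.3183; d2 <- -8.149; d3 <- -0.374; d4 <- 0.8861
  x <- d2 * v + d3
  d1 * log(x + sqrt(x * x + 1)) + d4
}

#' Normalized active force-length curve (f(1) = 1)
#' @param l normalized fiber length. @return numeric like `l`.
#' @export
force_length <- function(l) fl_active_raw(l) / fl_active_raw(1)

#' Normalized force-velocity curve (f(0) = 1; v in fiber lengths/s over v_max)
#' @param v normalized fiber velocity (positive = lengthening).
#' @export
force_velocity <- function(v) pmax(fv_raw(v) / fv_raw(0), 0)

#' Passive force-length curve (0 at and below optimal length)
#' @param l normalized fiber length.
#' @export
force_passive <- function(l) {
  kpe <- 4; e0 <- 0.6
  pmax((exp(kpe * (l - 1) / e0) - 1) / (exp(kpe) - 1), 0)
}

# --- muscle-tendon parameters ----------------------------------------------

#' Muscle-tendon parameter record
#'
#' @param name muscle name.
#' @param f_max maximum isometric force (N).
#' @param l_opt optimal fiber length (m).
#' @param l_ts tendon slack length (m); the tendon is rigid.
#' @param pennation pennation angle at optimal fiber length (rad).
#' @param tau_act,tau_deact activation/deactivation time constants (s);
#'   `tau_act <= tau_deact` is required.
#' @param emd electromechanical delay (s).
#' @param emg_scale EMG normalization scale factor in (0, 1].
#' @param shape activation nonlinearity shape factor (dimensionless, > 0).
#' @return list of class `muscle_params`.
#' @export
muscle_params <- function(name, f_max, l_opt, l_ts, pennation = 0,
                          tau_act = 0.015, tau_deact = 0.060, emd = 0.04,
                          emg_scale = 1, shape = 1) {
  if (f_max <= 0 || l_opt <= 0 || l_ts <= 0)
    stop_gaitfes("f_max, l_opt, l_ts must be > 0 (muscle ", name, ")")
  if (tau_act > tau_deact)
    stop_gaitfes("tau_act must be <= tau_deact (muscle ", name, ")")
  if (emg_scale <= 0 || emg_scale > 1)
    stop_gaitfes("emg_scale must be in (0, 1] (muscle ", name, ")")
  structure(list(name = name, f_max = f_max, l_opt = l_opt, l_ts = l_ts,
                 pennation = pennation, tau_act = tau_act,
                 tau_deact = tau_deact, emd = emd, emg_scale = emg_scale,
                 shape = shape), class = "muscle_params")
}

# --- activation dynamics ----------------------------------------------------

activation_nonlin <- function(a, shape) {
  if (abs(shape) < 1e-8) return(a)
  (exp(shape * a) - 1) / (exp(shape) - 1)
}

activation_nonlin_inv <- function(an, shape) {
  if (abs(shape) < 1e-8) return(an)
  log(1 + an * (exp(shape) - 1)) / shape
}

#' First-order activation dynamics with activation nonlinearity
#'
#' Bilinear first-order dynamics
#' `da/dt = (u - a) * (u / tau_act + (1 - u) / tau_deact)` integrated with an
#' exponential (exact-for-constant-input) update per step, followed by the
#' static nonlinearity `(exp(S a) - 1) / (exp(S) - 1)`. The excitation series
#' is assumed already delayed by the electromechanical delay.
#'
#' @param excitation series in `[0, 1]` on a uniform time grid. May be a
#'   matrix (columns = muscles sharing `dt`; `params` then a list per column).
#' @param params a `muscle_params` (or list of them for matrix input).
#' @param dt time step (s), > 0.
#' @param a0 initial activation; defaults to the first excitation sample.
#' @return activation series in `[0, 1]`, same shape as `excitation`.
#' @export
activation_dynamics <- function(excitation, params, dt, a0 = NULL) {
  if (dt <= 0) stop_gaitfes("dt must be > 0")
  u <- as.matrix(excitation)
  u <- pmin(pmax(u, 0), 1)
  plist <- if (inherits(params, "muscle_params")) rep(list(params), ncol(u)) else params
  ta <- vapply(plist, `[[`, 0, "tau_act")
  td <- vapply(plist, `[[`, 0, "tau_deact")
  sh <- vapply(plist, `[[`, 0, "shape")
  n <- nrow(u)
  a <- matrix(0, n, ncol(u))
  a[1, ] <- if (is.null(a0)) u[1, ] else a0
  for (k in 2:n) {
    rate <- u[k, ] / ta + (1 - u[k, ]) / td
    a[k, ] <- u[k, ] + (a[k - 1, ] - u[k, ]) * exp(-dt * rate)
  }
  for (j in seq_len(ncol(a))) a[, j] <- activation_nonlin(a[, j], sh[j])
  a <- pmin(pmax(a, 0), 1)
  if (is.matrix(excitation)) a else as.numeric(a)
}

# Inverse of activation_dynamics: excitation that reproduces a given (smooth,
# periodic) activation trajectory under the same model; used by the synthetic
# generator so EMG envelopes are consistent with ground-truth activations.
# Solves the *discrete* update a_k = u + (a_{k-1} - u) exp(-dt r(u)) exactly
# (vectorized Newton from the continuous-ODE estimate), so the forward pass
# reproduces the series up to clamping.
invert_activation_dynamics <- function(a_nl, params, dt) {
  a <- activation_nonlin_inv(pmin(pmax(a_nl, 0), 1), params$shape)
  n <- length(a)
  a_prev <- a[c(n, 1:(n - 1))]
  adot <- (a[c(2:n, 1)] - a_prev) / (2 * dt)
  b <- 1 / params$tau_act - 1 / params$tau_deact
  cc <- 1 / params$tau_deact
  u <- if (abs(b) < 1e-12) a + adot / cc else {
    disc <- pmax((cc - a * b)^2 + 4 * b * (a * cc + adot), 0)
    (-(cc - a * b) + sqrt(disc)) / (2 * b)
  }
  u <- pmin(pmax(u, 0), 1)
  f <- function(u) u + (a_prev - u) * exp(-dt * (u / params$tau_act +
                                                   (1 - u) / params$tau_deact)) - a
  # damped Newton with clamped steps: the discrete map is monotone only near
  # the solution, and the ODE estimate starts close
  h <- 1e-6
  for (it in 1:25) {
    fu <- f(u)
    dfu <- (f(pmin(u + h, 1)) - f(pmax(u - h, 0))) /
      (pmin(u + h, 1) - pmax(u - h, 0))
    dfu <- sign(dfu + (dfu == 0)) * pmax(abs(dfu), 0.02)
    step <- pmin(pmax(fu / dfu, -0.03), 0.03)
    u <- pmin(pmax(u - step, 0), 1)
  }
  u
}

# Periodic time shift (used for electromechanical delay on cyclic data)
delay_periodic <- function(x, t, delay, t_end) {
  interp_periodic(t, x, t - delay, t_end)
}

# --- Hill force --------------------------------------------------------------

# Batched rigid-tendon force with a smooth fiber-length floor (OCP-internal).
hill_force_batched <- function(a, lmt, vmt, p, guard = 1e-4) {
  w <- p$l_opt * sin(p$pennation)
  proj <- smooth_pos(lmt - p$l_ts, guard)
  lf <- sqrt(proj^2 + w^2)
  cosa <- proj / pmax(lf, 1e-9)
  ln <- lf / p$l_opt
  vn <- (vmt * cosa) / (10 * p$l_opt)
  p$f_max * (a * force_length(ln) * force_velocity(vn) + force_passive(ln)) * cosa
}

#' Rigid-tendon Hill-type muscle force
#'
#' Fiber kinematics follow from the muscle-tendon length with tendon fixed at
#' slack length and a constant-thickness pennation model:
#' `l_fiber = sqrt((l_mt - l_ts)^2 + (l_opt sin(pennation))^2)`.
#' Force is `F_max * (a * f_len * f_vel + f_pas) * cos(pennation_current)`.
#'
#' @param a activation in `[0, 1]`.
#' @param lmt muscle-tendon length (m).
#' @param vmt muscle-tendon lengthening velocity (m/s).
#' @param params a `muscle_params`.
#' @return fiber force along the tendon (N), >= 0.
#' @export
muscle_force <- function(a, lmt, vmt, params) {
  if (any(lmt - params$l_ts <= 0))
    stop_gaitfes("non-positive fiber length for muscle ", params$name)
  hill_force_batched(a, lmt, vmt, params, guard = 0)
}

# --- default muscle set ------------------------------------------------------

# Path specs: ordered points (segment, local xy). Lengths and moment arms
# come from straight-line point paths; `spans` lists the joint coordinates
# the muscle crosses.
.leg_paths <- function(side) {
  sfx <- paste0("_", side)
  sg <- function(base) paste0(base, sfx)
  pt <- function(segment, x, y) list(segment = segment, p = c(x, y))
  path <- function(name, spans, ...) list(name = paste0(name, sfx),
                                          spans = paste0(spans, sfx),
                                          points = list(...))
  list(
    path("iliopsoas", "hip", pt("pelvis", 0.05, -0.05), pt(sg("thigh"), 0.02, -0.10)),
    path("glutei", "hip", pt("pelvis", -0.06, -0.02), pt(sg("thigh"), -0.02, -0.10)),
    path("hamstrings", c("hip", "knee"), pt("pelvis", -0.06, -0.04),
         pt(sg("shank"), -0.025, -0.05)),
    path("rectus_femoris", c("hip", "knee"), pt("pelvis", 0.045, -0.03),
         pt(sg("thigh"), 0.05, -0.40), pt(sg("shank"), 0.035, -0.06)),
    path("vasti", "knee", pt(sg("thigh"), 0.02, -0.15), pt(sg("thigh"), 0.05, -0.40),
         pt(sg("shank"), 0.035, -0.06)),
    path("bifemsh", "knee", pt(sg("thigh"), -0.02, -0.15), pt(sg("shank"), -0.025, -0.05)),
    path("gastrocnemius", c("knee", "ankle"), pt(sg("thigh"), -0.02, -0.39),
         pt(sg("foot"), -0.05, -0.05)),
    path("soleus", "ankle", pt(sg("shank"), -0.02, -0.15), pt(sg("foot"), -0.05, -0.05)),
    path("tibialis_anterior", "ankle", pt(sg("shank"), 0.03, -0.20),
         pt(sg("foot"), 0.08, -0.055))
  )
}

.muscle_base <- data.frame(
  base = c("iliopsoas", "glutei", "hamstrings", "rectus_femoris", "vasti",
           "bifemsh", "gastrocnemius", "soleus", "tibialis_anterior"),
  f_max = c(1500, 2000, 2500, 1200, 3500, 800, 2500, 3500, 1200),
  l_opt = c(0.12, 0.14, 0.14, 0.12, 0.11, 0.12, 0.09, 0.08, 0.09),
  stringsAsFactors = FALSE)

#' Default muscle set for the planar skeleton (9 muscles per leg)
#'
#' Builds the muscle path specifications and `muscle_params` for both legs.
#' Tendon slack lengths are set so that fibers sit at optimal length in a
#' neutral mid-stance-like pose.
#'
#' @param skel a `planar_skeleton`.
#' @return list with `paths` (named list of path specs) and `params`
#'   (named list of `muscle_params`), in matching order.
#' @export
default_muscles <- function(skel) {
  paths <- c(.leg_paths("r"), .leg_paths("l"))
  names(paths) <- vapply(paths, `[[`, "", "name")
  ref_q <- rep(0, length(skel$coords))
  ref_q[match(c("hip_r", "hip_l"), skel$coords)] <- 0.2
  ref_q[match(c("knee_r", "knee_l"), skel$coords)] <- 0.3
  params <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    base <- sub("_[rl]$", "", paths[[i]]$name)
    row <- .muscle_base[.muscle_base$base == base, ]
    l_ref <- path_length(skel, paths[[i]], ref_q)
    params[[i]] <- muscle_params(paths[[i]]$name, f_max = row$f_max,
                                 l_opt = row$l_opt,
                                 l_ts = max(l_ref - row$l_opt, 0.01))
  }
  names(params) <- names(paths)
  list(paths = paths, params = params)
}
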