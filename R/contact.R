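# Deformable foot-ground contact: nonlinear spring-damper elements on a
# planar two-segment foot, with tanh-smoothed Coulomb + viscous friction and
# a treadmill belt term.
#
# Force law per element (differentiable everywhere):
#   depth  d+ = smooth_pos(-height)
#   normal N  = (k * d+^p + k_lin * d+) * smooth_pos(1 + c * ddot, .)
# The small linear term k_lin regularizes the otherwise flat gradient of the
# cubic law at first touchdown (it contributes a few N at working depths);
# normal force is never negative.
#   tangential F_t = -N * (mu_d * tanh(v_slip / v_smooth) + mu_v * v_slip)
# with v_slip the element velocity relative to the belt surface. Gait
# problems are solved in the progression frame where the belt surface is
# stationary (belt_speed = 0); the field exists so a lab-frame treadmill can
# be modelled directly.

#' Contact parameter set
#'
#' @param spacing element grid spacing along the sole (m).
#' @param stiffness stiffness coefficient k (N/m^p).
#' @param exponent stiffness exponent p.
#' @param damping damping coefficient c (s/m).
#' @param mu_d dynamic (Coulomb) friction coefficient.
#' @param mu_v viscous friction coefficient (s/m).
#' @param v_smooth slip-smoothing velocity (m/s).
#' @param belt_speed belt surface velocity in the simulation frame (m/s).
#' @param depth_smooth penetration smoothing half-width (m).
#' @return list of class `contact_params`.
#' @export
contact_params <- function(spacing = 0.04, stiffness = 1e9, exponent = 3,
                           damping = 1.0, mu_d = 0.8, mu_v = 0.5,
                           v_smooth = 0.05, belt_speed = 0,
                           depth_smooth = 2e-4, lin_stiffness = 3000) {
  if (spacing <= 0 || stiffness <= 0) stop_gaitfes("stiffness and spacing must be > 0")
  if (mu_d < 0 || mu_v < 0) stop_gaitfes("friction coefficients must be >= 0")
  if (v_smooth <= 0) stop_gaitfes("v_smooth must be > 0")
  structure(list(spacing = spacing, stiffness = stiffness, exponent = exponent,
                 damping = damping, mu_d = mu_d, mu_v = mu_v,
                 v_smooth = v_smooth, belt_speed = belt_speed,
                 depth_smooth = depth_smooth, lin_stiffness = lin_stiffness),
            class = "contact_params")
}

#' Place contact elements under a planar foot
#'
#' Generates a 1-D grid over the bounding interval of the foot outline,
#' retains grid points whose centers lie inside the outline, and assigns each
#' to the hindfoot or toes segment according to where it resides (split at
#' the metatarsophalangeal joint).
#'
#' @param outline list with `x_range = c(lo, hi)` (m, hindfoot frame along the
#'   sole), optional `keep` — list of allowed x-intervals (defaults to the
#'   full range), and `mtp_x` — the toe-joint x position.
#' @param spacing grid spacing (m), > 0.
#' @return `contact_element_set`: data.frame with element `x` (in the frame of
#'   its own segment), `segment` ("hindfoot"/"toes"), plus attributes.
#' @export
place_contact_elements <- function(outline, spacing) {
  if (spacing <= 0) stop_gaitfes("spacing must be > 0")
  xr <- outline$x_range
  if (!is.numeric(xr) || length(xr) != 2 || xr[2] <= xr[1])
    stop_gaitfes("degenerate foot outline")
  xs <- seq(xr[1], xr[2], by = spacing)
  keep <- outline$keep %||% list(xr)
  inside <- vapply(xs, function(x)
    any(vapply(keep, function(iv) x >= iv[1] - 1e-12 && x <= iv[2] + 1e-12, TRUE)),
    TRUE)
  xs <- xs[inside]
  if (!length(xs)) stop_gaitfes("zero contact elements retained")
  mtp <- outline$mtp_x %||% xr[2]
  segment <- ifelse(xs < mtp, "hindfoot", "toes")
  x_local <- ifelse(segment == "hindfoot", xs, xs - mtp)
  structure(data.frame(x = x_local, x_outline = xs, segment = segment,
                       stringsAsFactors = FALSE),
            class = c("contact_element_set", "data.frame"))
}

#' Default element set: 6 hindfoot + 3 toe elements
#' @param skel a `planar_skeleton` (for foot dimensions).
#' @export
default_contact_elements <- function(skel = default_skeleton()) {
  place_contact_elements(list(x_range = c(-0.054, 0.2181), mtp_x = skel$mtp_x),
                         spacing = 0.034)
}

#' Per-element contact forces
#'
#' @param height element height above the ground (m; negative = penetration).
#' @param vx,vy element velocity in the simulation frame (m/s).
#' @param params a `contact_params`.
#' @return list with `normal` (N, >= 0) and `tangential` (N, along +x).
#'   Inputs may be matrices (batched).
#' @export
element_forces <- function(height, vx, vy, params) {
  d <- smooth_pos(-height, params$depth_smooth)
  rate_fac <- smooth_pos(1 - params$damping * vy, 0.05)
  normal <- (params$stiffness * d^params$exponent +
             params$lin_stiffness * d) * rate_fac
  v_slip <- vx - params$belt_speed
  tangential <- -normal * (params$mu_d * tanh(v_slip / params$v_smooth) +
                           params$mu_v * v_slip)
  list(normal = normal, tangential = tangential)
}

# Batched element kinematics + forces + generalized-load list for one foot.
# Returns forces per element and the point-load entries for the dynamics.
foot_contact_batched <- function(skel, fk, elements, params, side) {
  foot_seg <- paste0("foot_", side); toe_seg <- paste0("toe_", side)
  loads <- list()
  Fx_tot <- 0; Fy_tot <- 0; Mz_tot <- 0; xF_tot <- 0
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    if (e$segment == "hindfoot") {
      seg <- foot_seg; px <- e$x; py <- skel$foot_sole_y
    } else {
      seg <- toe_seg; px <- e$x; py <- 0
    }
    pk <- segment_point_kin(fk[[seg]], px, py)
    f <- element_forces(pk$y, pk$vx, pk$vy, params)
    loads[[length(loads) + 1]] <- list(segment = seg, x = pk$x, y = pk$y,
                                       fx = f$tangential, fy = f$normal)
    Fx_tot <- Fx_tot + f$tangential
    Fy_tot <- Fy_tot + f$normal
    Mz_tot <- Mz_tot + pk$x * f$normal - pk$y * f$tangential
    xF_tot <- xF_tot + pk$x * f$normal
  }
  list(loads = loads, fx = Fx_tot, fy = Fy_tot, mz = Mz_tot, x_weighted = xF_tot)
}

#' Aggregate per-foot ground reactions from the contact model
#'
#' @param skel a `planar_skeleton`.
#' @param q,qd coordinate and rate vectors (length 11).
#' @param elements a `contact_element_set`.
#' @param params a `contact_params`.
#' @return per-foot list (`r`, `l`) with `fx` (anterior-posterior force, N),
#'   `fy` (vertical force, N), `mz` (free moment about the ground-frame
#'   origin, N m), `cop` (centre of pressure x, m; `NA` and `cop_defined =
#'   FALSE` when vertical force <= 1 N).
#' @export
aggregate_ground_reactions <- function(skel, q, qd, elements, params) {
  fk <- fk_batched(skel, as_coord_array(q), as_coord_array(qd), NULL)
  out <- list()
  for (side in c("r", "l")) {
    fc <- foot_contact_batched(skel, fk, elements, params, side)
    fy <- fc$fy[1, 1]
    defined <- fy > 1
    out[[side]] <- list(fx = fc$fx[1, 1], fy = fy, mz = fc$mz[1, 1],
                        cop = if (defined) fc$x_weighted[1, 1] / fy else NA_real_,
                        cop_defined = defined)
  }
  out
}
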