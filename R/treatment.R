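# FastFES treatment design: baseline asymmetry-minimization problem and the
# stimulation treatment optimal control problems (standard muscles with
# standard or free timing, two-muscle selection via the continuous
# stimulated-muscle count, and optimal stimulation of the selected pair),
# plus anterior-posterior impulse outcome metrics and report tables.

#' Anterior-posterior impulse metrics of a gait solution
#'
#' Simpson-quadrature integrals of the fore-aft ground reaction over the
#' cycle, per leg: signed impulse, propulsive (positive part) and braking
#' (negative part) impulses and peaks, and the inter-leg difference of the
#' signed impulse. Paretic = right leg.
#'
#' @param outputs gait outputs (from [gait_outputs()]) with `grf` and `qw`.
#' @return list of class `treatment_outcome`.
#' @export
ap_impulse_metrics <- function(outputs) {
  w <- outputs$qw
  met <- list()
  for (sd in c("r", "l")) {
    fx <- outputs$grf[[sd]]$fx
    met[[sd]] <- list(
      impulse = sum(fx * w),
      prop_impulse = sum(pmax(fx, 0) * w),
      brake_impulse = sum(pmin(fx, 0) * w),
      prop_peak = max(fx), brake_peak = min(fx))
  }
  met$diff <- abs(met$l$impulse - met$r$impulse)
  met$total <- met$l$impulse + met$r$impulse
  structure(met, class = "treatment_outcome")
}

#' Percent change / percent reduction with table-style rounding
#'
#' `form = "change"` gives `100 * (treated - baseline) / baseline` (signed);
#' `form = "reduction"` gives `100 * (baseline - treated) / baseline`.
#' Rounding is half-away-from-zero, as printed in clinical tables.
#'
#' @param baseline,treated values; baseline must be nonzero.
#' @param decimals decimal places.
#' @param form `"change"` or `"reduction"`.
#' @return rounded percentage.
#' @export
percent_change <- function(baseline, treated, decimals = 1,
                           form = c("change", "reduction")) {
  form <- match.arg(form)
  if (any(baseline == 0)) stop_gaitfes("zero baseline in percent change")
  p <- if (form == "change") 100 * (treated - baseline) / baseline
       else 100 * (baseline - treated) / baseline
  round_half_away(p, decimals)
}

# asymmetry residual: signed AP-impulse difference between the legs
asym_residual_fn <- function(model, opts, w_asym) {
  fn <- ap_impulse_diff_fn(model, opts)
  function(traj) sqrt(w_asym) * fn(traj)
}

# Shared problem builder: the verification formulation (jerk cost, dynamics
# + moment-match constraints, bounded synergy-activation changes,
# periodicity) with the AP-asymmetry cost term and optional stimulation
# statics.
build_treatment_ocp <- function(model, C_cal, w_asym, act_band = 0.1,
                                stim = NULL, N) {
  n_syn <- model$n_syn
  n_u <- 2 * n_syn
  n_s <- if (is.null(stim)) 0 else 3 * length(stim$muscle_idx)
  opts <- list(muscle_driven = TRUE, contact_source = "model",
               W_source = "model", stim = stim, eval_all = TRUE)
  sc <- gait_scales()
  ocp <- ocp_definition(n_q = 11, n_u = n_u, n_s = n_s, N = N,
                        t_end = model$t_end, scale_q = sc$q, scale_qd = sc$qd,
                        scale_qdd = sc$qdd, scale_jerk = sc$jerk,
                        scale_u = 0.5,
                        scale_s = rep(c(0.35, 0.3, 0.3), max(1, length(stim$muscle_idx)))[seq_len(max(n_s, 1))][seq_len(n_s)])
  ocp <- add_cost(ocp, "jerk", 1, jerk_cost_fn())
  ocp <- add_cost(ocp, "jerk_smooth", 2, jerk_smooth_fn())
  ocp <- add_cost(ocp, "mid_dynamics", 0.3, mid_dynamics_fn(model, opts))
  ocp <- add_cost(ocp, "toe_torque", 0.2, toe_torque_fn(model, opts))
  if (w_asym > 0)
    ocp <- add_cost(ocp, "ap_asymmetry", 1, asym_residual_fn(model, opts, w_asym))
  ocp <- add_path_constraint(ocp, "pelvis_dynamics", pelvis_residual_fn(model, opts))
  ocp <- add_path_constraint(ocp, "pelvis_x_mid", pelvis_x_mid_fn(model, opts))
  ocp <- add_path_constraint(ocp, "moment_match", moment_match_fn(model, opts))
  ocp <- add_path_constraint(ocp, "synergy_activation_band", function(tr) {
    do.call(rbind, lapply(seq_len(n_u), function(k)
      abs(tr$u[[k]][tr$node_idx, , drop = FALSE] - C_cal[, k]) - act_band)) / 0.2
  }, type = "ineq")
  if (!is.null(stim)) {
    # total activation of stimulated muscles must stay below one
    ocp <- add_path_constraint(ocp, "total_activation", function(tr) {
      g <- gait_pipeline(model, tr, opts)
      do.call(rbind, lapply(stim$muscle_idx, function(mi)
        (g$act[[mi]][g$node_rows, , drop = FALSE] - 1) / 0.2))
    }, type = "ineq")
  }
  ocp <- add_gait_periodicity(ocp, model, n_u = n_u)
  ocp <- set_bounds(ocp, "u", 0, 2)
  list(ocp = ocp, opts = opts)
}

#' Calibrate stimulation waveform shapes for a muscle set
#'
#' One calibration per muscle at its nominal timing; the shape parameters
#' are then held fixed while amplitude and timing vary in the treatment
#' problems.
#'
#' @param model a `gait_model`.
#' @param muscles muscle names (paretic side).
#' @param nominal list per muscle: `c(t_on, duration)` in seconds.
#' @return list of shape parameter sets (c1, c2, offsets, fit RMSE).
#' @export
calibrate_stim_shapes <- function(model, muscles, nominal) {
  shapes <- vector("list", length(muscles))
  for (j in seq_along(muscles)) {
    p <- model$muscles$params[[muscles[j]]]
    t_on <- nominal[[j]][1]
    t_off <- (t_on + nominal[[j]][2]) %% model$t_end
    shapes[[j]] <- calibrate_stim_shape(p, t_on, t_off, model$t_end)
  }
  names(shapes) <- muscles
  shapes
}

# default nominal FastFES timing for the virtual patient (seconds):
# plantarflexor burst in late stance, dorsiflexor through swing (wrapping)
default_stim_nominal <- function(model, muscles) {
  t_end <- model$t_end
  lapply(muscles, function(nm) {
    if (grepl("tibialis", nm)) c(0.60 * t_end, 0.45 * t_end)
    else c(0.44 * t_end, 0.12 * t_end)
  })
}

stim_spec_for <- function(model, muscles, shapes) {
  list(muscle_idx = match(muscles, model$muscle_names),
       shapes = shapes,
       static_rows = lapply(seq_along(muscles), function(j) (j - 1) * 3 + 1:3))
}

#' Baseline treatment optimization (no stimulation)
#'
#' The verification problem plus a cost term on the squared inter-leg AP
#' impulse difference. The asymmetry weight is the largest value from a
#' power-of-ten ladder that keeps the joint-angle RMSE against the
#' verification solution within `angle_tol_deg`.
#'
#' @param model personalized `gait_model`.
#' @param verify_res result of [verify_model()] (warm start + reference).
#' @param C_cal calibrated synergy activations at the nodes.
#' @param w_ladder candidate asymmetry weights (ascending).
#' @param angle_tol_deg allowed motion change (deg RMSE).
#' @param N mesh intervals.
#' @return list: `solution`, `outputs`, `outcome`, `w_asym`, `opts`.
#' @export
baseline_optimization <- function(model, verify_res, C_cal = NULL,
                                  w_ladder = c(3e-4, 3e-3),
                                  angle_tol_deg = 2, N = 14, tol = 1e-6,
                                  max_outer = 8, max_inner = 40,
                                  verbose = FALSE) {
  if (is.null(C_cal)) {
    tn <- verify_res$outputs$t[seq(1, length(verify_res$outputs$t), 2)]
    C_cal <- sapply(seq_len(2 * model$n_syn), function(k)
      interp_periodic(verify_res$outputs$t, verify_res$outputs$C[, k], tn,
                      model$t_end))
  }
  q_ref <- verify_res$outputs$q[, 4:11]
  best <- NULL
  z0 <- NULL
  for (w in w_ladder) {
    bt <- build_treatment_ocp(model, C_cal, w_asym = w, N = N)
    nlp <- transcribe(bt$ocp)
    if (is.null(z0)) z0 <- warm_start_from(nlp, verify_res$solution)
    sol <- solve_ocp(nlp, z0, tol = tol, max_outer = max_outer,
                     max_inner = max_inner, verbose = verbose)
    out <- gait_outputs(model, sol, bt$opts)
    rmse <- sqrt(mean((out$q[, 4:11] - q_ref)^2)) * 180 / pi
    cand <- list(solution = sol, outputs = out,
                 outcome = ap_impulse_metrics(out), w_asym = w,
                 opts = bt$opts, angle_rmse_vs_verification = rmse,
                 C_cal = C_cal)
    if (rmse <= angle_tol_deg) best <- cand else break
    z0 <- sol$z
  }
  if (is.null(best)) best <- cand
  best
}

#' Optimize stimulation of two given muscles
#'
#' Adds step-like stimulation (amplitude, on-time, duration as static
#' parameters) on top of the synergy activations of the two muscles, with
#' the total-activation path constraint, and minimizes joint jerk plus AP
#' force asymmetry.
#'
#' @param model personalized `gait_model`.
#' @param base_res result of [baseline_optimization()].
#' @param muscles two paretic-side muscle names.
#' @param timing `"standard"` (on-time within +-0.05 s of nominal, duration
#'   fixed) or `"free"` (amplitude, on-time, and duration all free,
#'   wrap-around permitted).
#' @param nominal nominal `c(t_on, duration)` per muscle (s).
#' @param shapes calibrated waveform shapes (from [calibrate_stim_shapes()]).
#' @param N mesh intervals.
#' @return list: `solution`, `outputs`, `outcome`, `profiles`
#'   (per-muscle `stimulation_profile`), `opts`.
#' @export
optimize_stimulation <- function(model, base_res, muscles,
                                 timing = c("standard", "free"),
                                 nominal = NULL, shapes = NULL, N = 14,
                                 tol = 1e-6, max_outer = 7, max_inner = 35,
                                 verbose = FALSE) {
  timing <- match.arg(timing)
  if (is.null(nominal)) nominal <- default_stim_nominal(model, muscles)
  if (is.null(shapes)) shapes <- calibrate_stim_shapes(model, muscles, nominal)
  stim <- stim_spec_for(model, muscles, shapes)
  bt <- build_treatment_ocp(model, base_res$C_cal, w_asym = base_res$w_asym,
                            stim = stim, N = N)
  t_end <- model$t_end
  lo <- hi <- numeric(0)
  s0 <- numeric(0)
  for (j in seq_along(muscles)) {
    t_on <- nominal[[j]][1]; dur <- nominal[[j]][2]
    if (timing == "standard") {
      lo <- c(lo, 0, t_on - 0.05, dur); hi <- c(hi, 0.7, t_on + 0.05, dur)
    } else {
      lo <- c(lo, 0, -0.2 * t_end, 0.03); hi <- c(hi, 0.7, 1.2 * t_end, 0.8 * t_end)
    }
    s0 <- c(s0, 0.2, t_on, dur)
  }
  bt$ocp <- set_bounds(bt$ocp, "s", lo, hi)
  nlp <- transcribe(bt$ocp)
  z0 <- warm_start_from(nlp, base_res$solution, s0 = s0)
  sol <- solve_ocp(nlp, z0, tol = tol, max_outer = max_outer,
                   max_inner = max_inner, verbose = verbose)
  out <- gait_outputs(model, sol, bt$opts)
  profiles <- lapply(seq_along(muscles), function(j) {
    s <- sol$s[(j - 1) * 3 + 1:3]
    stimulation_profile(amplitude = min(max(s[1], 0), 0.7), t_on = s[2],
                        t_off = s[2] + s[3], t_end = t_end,
                        c1 = shapes[[j]]$c1, c2 = shapes[[j]]$c2,
                        t_offset1 = shapes[[j]]$t_offset1,
                        t_offset2 = shapes[[j]]$t_offset2)
  })
  names(profiles) <- muscles
  list(solution = sol, outputs = out, outcome = ap_impulse_metrics(out),
       profiles = profiles, opts = bt$opts, muscles = muscles,
       nominal = nominal, shapes = shapes)
}

#' Select the best two muscles to stimulate
#'
#' All measured paretic-leg muscles receive stimulation parameters
#' (amplitude, on-time, duration); a terminal constraint holds the
#' continuous stimulated-muscle count `sum(1 - exp(-4 A_i))` at or below
#' two plus a small tolerance. Returns the two muscles with the largest
#' optimized amplitudes and the full amplitude spectrum.
#'
#' @param model personalized `gait_model`.
#' @param base_res result of [baseline_optimization()].
#' @param candidates candidate muscle names (default: measured paretic
#'   muscles; predicted-status muscles are never candidates).
#' @param count_tol tolerance on the muscle count (default 0.1).
#' @param N mesh intervals.
#' @return list: `muscles` (two names), `amplitudes` (full spectrum),
#'   `count`, `solution`, `outcome`.
#' @export
select_muscles <- function(model, base_res, candidates = NULL,
                           count_tol = 0.1, N = 14, tol = 1e-6,
                           max_outer = 7, max_inner = 35, verbose = FALSE) {
  if (is.null(candidates)) {
    par_mus <- model$muscle_names[model$muscle_side == "r"]
    candidates <- par_mus[model$emg_status[par_mus] == "measured"]
  } else {
    bad <- candidates[model$emg_status[candidates] == "predicted"]
    if (length(bad)) stop_gaitfes("predicted-status muscles cannot be ",
                                  "stimulation candidates: ",
                                  paste(bad, collapse = ", "))
  }
  if (length(candidates) < 2) stop_gaitfes("need at least 2 candidate muscles")
  nominal <- default_stim_nominal(model, candidates)
  shapes <- calibrate_stim_shapes(model, candidates, nominal)
  stim <- stim_spec_for(model, candidates, shapes)
  bt <- build_treatment_ocp(model, base_res$C_cal, w_asym = base_res$w_asym,
                            stim = stim, N = N)
  amp_rows <- vapply(stim$static_rows, function(r) r[1], numeric(1))
  bt$ocp <- add_terminal_constraint(bt$ocp, "stimulated_muscle_count",
    function(tr) {
      n <- 0
      for (r in amp_rows) n <- n + (1 - exp(-4 * tr$s[r, , drop = FALSE]))
      (n - (2 + count_tol))
    }, type = "ineq")
  t_end <- model$t_end
  lo <- rep(c(0, -0.2 * t_end, 0.03), length(candidates))
  hi <- rep(c(0.7, 1.2 * t_end, 0.8 * t_end), length(candidates))
  bt$ocp <- set_bounds(bt$ocp, "s", lo, hi)
  nlp <- transcribe(bt$ocp)
  s0 <- as.numeric(vapply(seq_along(candidates), function(j)
    c(0.1, nominal[[j]][1], nominal[[j]][2]), numeric(3)))
  z0 <- warm_start_from(nlp, base_res$solution, s0 = s0)
  sol <- solve_ocp(nlp, z0, tol = tol, max_outer = max_outer,
                   max_inner = max_inner, verbose = verbose)
  amps <- sol$s[amp_rows]
  names(amps) <- candidates
  sel <- names(sort(amps, decreasing = TRUE))[1:2]
  out <- gait_outputs(model, sol, bt$opts)
  list(muscles = sel, amplitudes = amps,
       count = effective_muscle_count(pmax(amps, 0)),
       solution = sol, outputs = out, outcome = ap_impulse_metrics(out))
}

#' Outcome report tables for the treatment sequence
#'
#' Emits the AP-impulse-difference table (with percent reduction relative to
#' baseline), the stimulation-parameter table (amplitude, on/off in % gait
#' cycle), and the propulsive/braking peak-and-impulse table with percent
#' changes. Values rounded to one decimal (half away from zero); percent
#' columns are recomputed from the unrounded values.
#'
#' @param baseline baseline result. @param treatments named list of
#'   treatment results (each with `outcome`, and `profiles` if stimulated).
#' @return list of data.frames: `ap_difference`, `stimulation`, `forces`.
#' @export
outcome_report <- function(baseline, treatments) {
  if (is.null(baseline$outcome)) stop_gaitfes("baseline outcome missing")
  for (nm in names(treatments))
    if (is.null(treatments[[nm]]$outcome))
      stop_gaitfes("missing outcome for treatment '", nm, "'")
  b <- baseline$outcome
  ap <- data.frame(problem = "baseline",
                   ap_impulse_difference = round_half_away(b$diff, 1),
                   reduction_pct = NA_real_, stringsAsFactors = FALSE)
  for (nm in names(treatments)) {
    d <- treatments[[nm]]$outcome$diff
    ap <- rbind(ap, data.frame(problem = nm,
                               ap_impulse_difference = round_half_away(d, 1),
                               reduction_pct = percent_change(b$diff, d,
                                                              form = "reduction")))
  }
  stim_tab <- NULL
  for (nm in names(treatments)) {
    pr <- treatments[[nm]]$profiles
    for (mus in names(pr)) {
      p <- pr[[mus]]
      stim_tab <- rbind(stim_tab, data.frame(
        problem = nm, muscle = mus, A = round_half_away(p$amplitude, 2),
        t_on_pct = round_half_away(time_to_percent(p$t_on, p$t_end), 0),
        t_off_pct = round_half_away(time_to_percent(p$t_off, p$t_end), 0)))
    }
  }
  frc <- NULL
  add_frc <- function(problem, oc, base_oc) {
    for (sd in c("r", "l")) {
      leg <- if (sd == "r") "paretic" else "non_paretic"
      for (kind in c("prop", "brake")) {
        pk <- oc[[sd]][[paste0(kind, "_peak")]]
        im <- oc[[sd]][[paste0(kind, "_impulse")]]
        frc <<- rbind(frc, data.frame(
          problem = problem, leg = leg, force = kind,
          peak = round_half_away(pk, 1), impulse = round_half_away(im, 1),
          peak_change_pct = if (is.null(base_oc)) NA_real_ else
            percent_change(base_oc[[sd]][[paste0(kind, "_peak")]], pk),
          impulse_change_pct = if (is.null(base_oc)) NA_real_ else
            percent_change(base_oc[[sd]][[paste0(kind, "_impulse")]], im)))
      }
    }
  }
  add_frc("baseline", b, NULL)
  for (nm in names(treatments)) add_frc(nm, treatments[[nm]]$outcome, b)
  list(ap_difference = ap, stimulation = stim_tab, forces = frc)
}

#' Run the full treatment-design sequence
#'
#' Baseline, standard muscles with standard timing, standard muscles with
#' free timing, two-muscle selection, and optimal stimulation of the
#' selected pair, each warm-started from its predecessor.
#'
#' @param model personalized `gait_model`.
#' @param verify_res verification result.
#' @param N mesh intervals.
#' @param verbose print solver progress.
#' @return list with all five results and the `outcome_report()` tables.
#' @export
design_treatment <- function(model, verify_res, N = 14, verbose = FALSE,
                             w_ladder = c(3e-4, 3e-3)) {
  std <- paste0(c("gastrocnemius", "tibialis_anterior"), "_r")
  base <- baseline_optimization(model, verify_res, N = N, verbose = verbose,
                                w_ladder = w_ladder)
  std_std <- optimize_stimulation(model, base, std, timing = "standard",
                                  N = N, verbose = verbose)
  std_opt <- optimize_stimulation(model, base, std, timing = "free",
                                  N = N, verbose = verbose)
  selection <- select_muscles(model, base, N = N, verbose = verbose)
  opt_opt <- optimize_stimulation(model, base, selection$muscles,
                                  timing = "free", N = N, verbose = verbose)
  report <- outcome_report(base, list(
    standard_standard = std_std, standard_optimal = std_opt,
    optimal_optimal = opt_opt))
  list(baseline = base, standard_standard = std_std,
       standard_optimal = std_opt, selection = selection,
       optimal_optimal = opt_opt, report = report)
}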