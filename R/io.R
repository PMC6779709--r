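# Plain-text interchange: trial CSV schema (markers / ground reactions /
# EMG + events YAML), model description YAML, and JSON serialization of
# synergy sets, stimulation profiles, and optimal control solutions.
# Side prefixes: P_ = paretic (right), N_ = non-paretic (left).

#' Write a gait trial to CSV + YAML files
#'
#' Creates `markers.csv`, `grf.csv`, `emg.csv`, and `events.yaml` in `dir`.
#' All time columns are in seconds.
#'
#' @param trial a `gait_trial`. @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_gait_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- data.frame(time = trial$t)
  for (nm in names(trial$markers)) {
    mk[[paste0(nm, "_x")]] <- trial$markers[[nm]][, 1]
    mk[[paste0(nm, "_y")]] <- trial$markers[[nm]][, 2]
  }
  utils::write.csv(mk, file.path(dir, "markers.csv"), row.names = FALSE)
  gr <- data.frame(time = trial$t,
                   P_fx = trial$grf$r$fx, P_fy = trial$grf$r$fy,
                   P_mz = trial$grf$r$mz, P_cop = trial$grf$r$cop,
                   N_fx = trial$grf$l$fx, N_fy = trial$grf$l$fy,
                   N_mz = trial$grf$l$mz, N_cop = trial$grf$l$cop)
  utils::write.csv(gr, file.path(dir, "grf.csv"), row.names = FALSE)
  em <- data.frame(time = trial$t)
  for (nm in colnames(trial$emg)) em[[nm]] <- trial$emg[, nm]
  utils::write.csv(em, file.path(dir, "emg.csv"), row.names = FALSE)
  yaml::write_yaml(c(trial$events, list(belt_speed = trial$belt_speed,
                                        t_end = trial$t_end)),
                   file.path(dir, "events.yaml"))
  invisible(dir)
}

#' Read a gait trial written by [write_gait_trial()]
#' @param dir directory containing the CSV/YAML files.
#' @return a `gait_trial` (without ground-truth fields).
#' @export
read_gait_trial <- function(dir) {
  mk <- utils::read.csv(file.path(dir, "markers.csv"))
  gr <- utils::read.csv(file.path(dir, "grf.csv"))
  em <- utils::read.csv(file.path(dir, "emg.csv"))
  ev <- yaml::read_yaml(file.path(dir, "events.yaml"))
  mnames <- unique(sub("_[xy]$", "", setdiff(names(mk), "time")))
  markers <- lapply(mnames, function(nm)
    cbind(mk[[paste0(nm, "_x")]], mk[[paste0(nm, "_y")]]))
  names(markers) <- mnames
  grf <- list(
    r = list(fx = gr$P_fx, fy = gr$P_fy, mz = gr$P_mz, cop = gr$P_cop),
    l = list(fx = gr$N_fx, fy = gr$N_fy, mz = gr$N_mz, cop = gr$N_cop))
  emg <- as.matrix(em[setdiff(names(em), "time")])
  structure(list(t = mk$time, markers = markers, grf = grf, emg = emg,
                 events = ev[setdiff(names(ev), c("belt_speed", "t_end"))],
                 belt_speed = ev$belt_speed, t_end = ev$t_end),
            class = "gait_trial")
}

#' Write a model description to YAML
#'
#' Serializes segments (with joint placements and inertia), muscle
#' parameters and path points, contact parameters, and synergy vectors.
#'
#' @param model a `gait_model`. @param path output file.
#' @export
write_model_yaml <- function(model, path) {
  seg <- lapply(model$skel$segments, function(s) {
    out <- list(mass = s$mass, inertia = s$inertia, com = as.numeric(s$com),
                length = s$length)
    if (!is.na(s$parent)) {
      out$parent <- s$parent
      out$joint_in_parent <- as.numeric(s$joint_in_parent)
      out$joint_coord <- s$joint_coord
      out$joint_sign <- s$joint_sign
    }
    out
  })
  mus <- lapply(names(model$muscles$params), function(nm) {
    p <- model$muscles$params[[nm]]
    pa <- model$muscles$paths[[nm]]
    list(f_max = p$f_max, l_opt = p$l_opt, l_ts = p$l_ts,
         pennation = p$pennation, tau_act = p$tau_act,
         tau_deact = p$tau_deact, emd = p$emd, emg_scale = p$emg_scale,
         shape = p$shape, spans = pa$spans,
         points = lapply(pa$points, function(pt)
           list(segment = pt$segment, p = as.numeric(pt$p))),
         emg_status = unname(model$emg_status[nm]))
  })
  names(mus) <- names(model$muscles$params)
  doc <- list(
    coords = model$skel$coords, gravity = model$skel$gravity,
    segments = seg, muscles = mus,
    contact = unclass(model$contact),
    t_end = model$t_end, belt_speed = model$belt_speed,
    n_syn = model$n_syn,
    synergy_vectors = if (!is.null(model$W))
      list(paretic = as.numeric(model$W$r), non_paretic = as.numeric(model$W$l),
           n_muscles = nrow(model$W$r)) else NULL)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a model description written by [write_model_yaml()]
#'
#' Rebuilds the `gait_model` (surrogate geometry is refitted from the path
#' models, so the YAML stays small and human-editable).
#'
#' @param path YAML file.
#' @param degree surrogate polynomial degree.
#' @return a `gait_model`.
#' @export
read_model_yaml <- function(path, degree = 4) {
  doc <- yaml::read_yaml(path)
  skel <- default_skeleton()
  for (nm in names(doc$segments)) {
    s <- doc$segments[[nm]]
    skel$segments[[nm]]$mass <- s$mass
    skel$segments[[nm]]$inertia <- s$inertia
    skel$segments[[nm]]$com <- unlist(s$com)
    if (!is.null(s$joint_in_parent))
      skel$segments[[nm]]$joint_in_parent <- unlist(s$joint_in_parent)
  }
  check_skeleton(skel)
  paths <- list(); params <- list(); status <- character(0)
  for (nm in names(doc$muscles)) {
    m <- doc$muscles[[nm]]
    paths[[nm]] <- list(name = nm, spans = unlist(m$spans),
                        points = lapply(m$points, function(pt)
                          list(segment = pt$segment, p = unlist(pt$p))))
    params[[nm]] <- muscle_params(nm, f_max = m$f_max, l_opt = m$l_opt,
                                  l_ts = m$l_ts, pennation = m$pennation,
                                  tau_act = m$tau_act, tau_deact = m$tau_deact,
                                  emd = m$emd, emg_scale = m$emg_scale,
                                  shape = m$shape)
    status[nm] <- m$emg_status
  }
  muscles <- list(paths = paths, params = params)
  sur <- build_surrogates(skel, muscles, degree = degree)
  cp <- do.call(contact_params, doc$contact[names(doc$contact) %in%
                                              names(formals(contact_params))])
  W <- NULL
  if (!is.null(doc$synergy_vectors)) {
    nm_ <- doc$synergy_vectors$n_muscles
    W <- list(r = matrix(unlist(doc$synergy_vectors$paretic), nm_),
              l = matrix(unlist(doc$synergy_vectors$non_paretic), nm_))
  }
  gait_model(skel, muscles, sur, cp, default_contact_elements(skel), W = W,
             t_end = doc$t_end, belt_speed = doc$belt_speed,
             n_syn = doc$n_syn, emg_status = status)
}

#' Serialize a synergy analysis to JSON
#' @param synergy a `synergy_set` (or list with W, C).
#' @param path output file.
#' @export
write_synergy_json <- function(synergy, path) {
  jsonlite::write_json(list(W = synergy$W, C = synergy$C,
                            vaf_total = synergy$vaf_total,
                            vaf_muscle = synergy$vaf_muscle),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Serialize stimulation profiles to JSON (table rows: muscle, A, t_on %, t_off %)
#' @param profiles named list of `stimulation_profile`.
#' @param path output file.
#' @export
write_stim_profiles_json <- function(profiles, path) {
  rows <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    list(muscle = nm, A = p$amplitude,
         t_on_pct = time_to_percent(p$t_on, p$t_end),
         t_off_pct = time_to_percent(p$t_off, p$t_end),
         c1 = p$c1, c2 = p$c2, t_offset1 = p$t_offset1, t_offset2 = p$t_offset2)
  })
  jsonlite::write_json(rows, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Serialize an optimal control solution to JSON
#'
#' Mesh, state/control trajectories at the collocation points, static
#' parameters, objective and per-term costs, and the violation report.
#'
#' @param solution an `ocp_solution`. @param path output file.
#' @export
write_solution_json <- function(solution, path) {
  tr <- solution$traj
  doc <- list(
    t = tr$t, t_end = tr$t_end,
    q = sapply(tr$q, function(M) M[, 1]),
    qd = sapply(tr$qd, function(M) M[, 1]),
    qdd = sapply(tr$qdd, function(M) M[, 1]),
    jerk = sapply(tr$jerk, function(M) M[, 1]),
    u = if (length(tr$u)) sapply(tr$u, function(M) M[, 1]) else NULL,
    s = solution$s,
    objective = solution$objective,
    cost_terms = solution$cost_terms,
    status = solution$status,
    max_violation = solution$max_violation,
    violations = as.list(solution$violations))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}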