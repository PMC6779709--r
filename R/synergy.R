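# EMG envelope processing, non-negative matrix factorization (multiplicative
# updates), rank selection by per-muscle VAF, and reconstruction of
# activations for muscles with missing EMG channels.

#' Process raw EMG to an excitation envelope
#'
#' High-pass filter, demean, rectify, low-pass filter — in that order, all
#' filtering zero-phase (forward-backward 4th-order Butterworth).
#'
#' @param raw raw EMG series.
#' @param rate sampling rate (Hz).
#' @param hp_cutoff high-pass cutoff (Hz), default 40.
#' @param lp_cutoff low-pass cutoff (Hz), default 6.
#' @return non-negative envelope series.
#' @export
process_emg <- function(raw, rate, hp_cutoff = 40, lp_cutoff = 6) {
  nyq <- rate / 2
  if (hp_cutoff >= nyq || lp_cutoff >= nyq)
    stop_gaitfes("filter cutoff must be below the Nyquist frequency (", nyq, " Hz)")
  if (rate <= 2 * hp_cutoff) stop_gaitfes("sampling rate must exceed twice hp_cutoff")
  # reflect-pad to suppress zero-phase filter edge transients
  np <- min(length(raw) - 1, ceiling(rate / 2))
  pad <- function(x) c(2 * x[1] - rev(x[2:(np + 1)]), x,
                       2 * x[length(x)] - rev(x[(length(x) - np):(length(x) - 1)]))
  core <- function(x) x[(np + 1):(np + length(raw))]
  bf_hp <- signal::butter(4, hp_cutoff / nyq, type = "high")
  x <- core(signal::filtfilt(bf_hp, pad(raw)))
  x <- x - mean(x)
  x <- abs(x)
  bf_lp <- signal::butter(4, lp_cutoff / nyq, type = "low")
  env <- core(signal::filtfilt(bf_lp, pad(x)))
  pmax(env, 0)
}

nmf_multiplicative <- function(X, k, W0, C0, max_iter = 2000, rel_tol = 1e-8,
                               trace = FALSE) {
  W <- W0; C <- C0
  eps <- 1e-12
  err_prev <- Inf
  hist <- if (trace) numeric(max_iter) else NULL
  for (it in seq_len(max_iter)) {
    WC <- W %*% C
    C <- C * (crossprod(W, X) / (crossprod(W, WC) + eps))
    WC <- W %*% C
    W <- W * (tcrossprod(X, C) / (W %*% tcrossprod(C) + eps))
    err <- sum((X - W %*% C)^2)
    if (trace) hist[it] <- err
    if (is.finite(err_prev) && (err_prev - err) <= rel_tol * max(err_prev, eps)) break
    err_prev <- err
  }
  list(W = W, C = C, sse = sum((X - W %*% C)^2), iterations = it,
       sse_trace = if (trace) hist[seq_len(it)] else NULL)
}

vaf_total <- function(X, W, C) 100 * (1 - sum((X - W %*% C)^2) / sum(X^2))

vaf_per_muscle <- function(X, W, C) {
  R <- X - W %*% C
  100 * (1 - rowSums(R^2) / pmax(rowSums(X^2), 1e-300))
}

#' Extract muscle synergies by non-negative matrix factorization
#'
#' Best-of-replicates multiplicative-update NMF (`X ~ W C`, all entries
#' non-negative). Deterministic for a given seed. Synergy vectors (columns of
#' `W`) are normalized to unit magnitude with the scale absorbed into `C`.
#'
#' @param activations muscles x time matrix, non-negative.
#' @param n_syn number of synergies, `< nrow(activations)`.
#' @param replicates random restarts (best SSE kept).
#' @param seed RNG seed.
#' @param max_iter,rel_tol update iteration cap and relative SSE tolerance.
#' @param W0,C0 optional warm start (used instead of the first replicate).
#' @return `synergy_set`: `W` (muscles x n_syn, unit-norm columns), `C`
#'   (n_syn x time), `vaf_total` (%), `vaf_muscle` (%), `sse`.
#' @export
extract_synergies <- function(activations, n_syn, replicates = 20, seed = 1,
                              max_iter = 2000, rel_tol = 1e-8,
                              W0 = NULL, C0 = NULL) {
  X <- as.matrix(activations)
  if (any(X < 0)) stop_gaitfes("activations must be non-negative")
  if (n_syn >= nrow(X)) stop_gaitfes("n_syn must be < number of muscles")
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  scale0 <- sqrt(mean(X) / n_syn + 1e-12)
  for (r in seq_len(replicates)) {
    if (r == 1 && !is.null(W0) && !is.null(C0)) {
      Wi <- W0; Ci <- C0
    } else {
      Wi <- matrix(stats::runif(nrow(X) * n_syn, 0.1, 1) * scale0, nrow(X), n_syn)
      Ci <- matrix(stats::runif(n_syn * ncol(X), 0.1, 1) * scale0, n_syn, ncol(X))
    }
    fit <- nmf_multiplicative(X, n_syn, Wi, Ci, max_iter, rel_tol)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  nrm <- sqrt(colSums(best$W^2))
  nrm[nrm < 1e-12] <- 1
  W <- sweep(best$W, 2, nrm, "/")
  C <- sweep(best$C, 1, nrm, "*")
  rownames(W) <- rownames(X)
  structure(list(W = W, C = C, sse = best$sse,
                 vaf_total = vaf_total(X, W, C),
                 vaf_muscle = vaf_per_muscle(X, W, C)),
            class = "synergy_set")
}

#' Choose the number of synergies by the per-muscle VAF rule
#'
#' Returns the smallest rank at which every individual muscle's VAF reaches
#' the threshold; also reports the smallest rank at which *total* VAF reaches
#' 95%, which is typically lower.
#'
#' @param activations muscles x time matrix, non-negative.
#' @param per_muscle_threshold per-muscle VAF threshold in (0, 100], default 95.
#' @param replicates,seed NMF settings per candidate rank.
#' @return list with `n_syn` (per-muscle rule), `n_syn_total` (total-VAF
#'   rule), and `vaf_by_rank` (per-rank total and minimum per-muscle VAF).
#' @export
choose_num_synergies <- function(activations, per_muscle_threshold = 95,
                                 replicates = 5, seed = 1) {
  if (per_muscle_threshold <= 0 || per_muscle_threshold > 100)
    stop_gaitfes("threshold must be in (0, 100]")
  X <- as.matrix(activations)
  if (any(X < 0)) stop_gaitfes("activations must be non-negative")
  n_mus <- nrow(X)
  n_syn <- NA_integer_; n_syn_total <- NA_integer_
  tab <- NULL
  for (k in seq_len(n_mus - 1)) {
    s <- extract_synergies(X, k, replicates = replicates, seed = seed + k)
    tab <- rbind(tab, data.frame(rank = k, vaf_total = s$vaf_total,
                                 vaf_min_muscle = min(s$vaf_muscle)))
    if (is.na(n_syn_total) && s$vaf_total >= 95) n_syn_total <- k
    if (is.na(n_syn) && min(s$vaf_muscle) >= per_muscle_threshold) {
      n_syn <- k
      if (!is.na(n_syn_total)) break
    }
  }
  list(n_syn = n_syn, n_syn_total = n_syn_total, vaf_by_rank = tab)
}

#' Apply the copied-channel rule to an EMG set
#'
#' Muscles with status `"copied"` receive their donor muscle's envelope
#' exactly (e.g. a hamstring head copied from its measured neighbour).
#'
#' @param emg matrix (time x channels, named columns).
#' @param status named status vector (`measured`/`copied`/`predicted`).
#' @param donors named character: copied muscle -> donor channel.
#' @return matrix with copied columns appended/overwritten.
#' @export
apply_copied_channels <- function(emg, status, donors) {
  for (nm in names(status)[status == "copied"]) {
    donor <- donors[[nm]]
    if (is.null(donor) || !donor %in% colnames(emg))
      stop_gaitfes("no donor channel for copied muscle ", nm)
    emg <- cbind(emg, structure(emg[, donor, drop = FALSE],
                                dimnames = list(NULL, nm)))
  }
  emg
}

#' Reconstruct activations for muscles with missing EMG
#'
#' Linear combination of the extracted synergy activations with per-muscle
#' non-negative weights, clamped to `[0, 1]`. Differentiable in the weights
#' away from the clamp.
#'
#' @param C synergy activations (n_syn x time).
#' @param weights weight vector (length n_syn) or matrix
#'   (n_missing x n_syn), non-negative.
#' @return predicted activation series (time vector, or n_missing x time).
#' @export
reconstruct_missing <- function(C, weights) {
  W <- if (is.matrix(weights)) weights else matrix(weights, 1)
  if (any(W < 0)) stop_gaitfes("synergy weights must be non-negative")
  if (ncol(W) != nrow(C)) stop_gaitfes("weight length ", ncol(W),
                                       " does not match n_syn = ", nrow(C))
  P <- pmin(pmax(W %*% C, 0), 1)
  if (is.matrix(weights)) P else as.numeric(P)
}
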