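# Small numerical helpers shared across modules.

#' Smooth positive part
#'
#' Differentiable approximation of `max(x, 0)` used by the contact force law
#' and by inequality penalties: `0.5 * (x + sqrt(x^2 + eps^2))`.
#'
#' @param x numeric vector/matrix.
#' @param eps smoothing half-width (same units as `x`).
#' @return object shaped like `x`.
#' @keywords internal
smooth_pos <- function(x, eps) 0.5 * (x + sqrt(x * x + eps * eps))

#' Round half away from zero
#'
#' Table-style rounding: 0.5 rounds to 1, -0.5 to -1 (base `round()` rounds
#' half to even, which does not reproduce printed clinical tables).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Trapezoidal integral on a (possibly non-uniform) grid
#' @param t abscissae. @param y ordinates (vector or matrix with rows = t).
#' @return scalar (or vector per column).
#' @keywords internal
trapz <- function(t, y) {
  dt <- diff(t)
  if (is.matrix(y)) {
    colSums((y[-1, , drop = FALSE] + y[-nrow(y), , drop = FALSE]) / 2 * dt)
  } else {
    sum((y[-1] + y[-length(y)]) / 2 * dt)
  }
}

#' Periodic linear interpolation
#'
#' Interpolates samples `y` given at times `t` (cycle of duration `t_end`,
#' t[1] maps to 0) onto query times `tq`, wrapping modulo the cycle.
#' @keywords internal
interp_periodic <- function(t, y, tq, t_end) {
  n <- length(t)
  # drop a duplicated endpoint (grids often include both 0 and t_end)
  if (abs((t[n] - t[1]) - t_end) < 1e-9) {
    t <- t[-n]
    y <- if (is.matrix(y)) y[-n, , drop = FALSE] else y[-n]
  }
  tt <- (tq - t[1]) %% t_end + t[1]
  # append wrap point so queries between t[n] and t_end interpolate to t[1]
  t2 <- c(t, t[1] + t_end)
  if (is.matrix(y)) {
    y2 <- rbind(y, y[1, , drop = FALSE])
    apply(y2, 2, function(col) stats::approx(t2, col, xout = tt, rule = 2)$y)
  } else {
    stats::approx(t2, c(y, y[1]), xout = tt, rule = 2)$y
  }
}

#' Rotate planar vectors
#' @keywords internal
rot2 <- function(theta, x, y) list(x = cos(theta) * x - sin(theta) * y,
                                   y = sin(theta) * x + cos(theta) * y)

#' Perpendicular (CCW) of planar vectors: perp(v) = (-v_y, v_x)
#' @keywords internal
perp2 <- function(x, y) list(x = -y, y = x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gaitfes <- function(...) stop(..., call. = FALSE)
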