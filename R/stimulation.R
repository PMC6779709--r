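# Functional electrical stimulation: smooth activation waveform for a step
# stimulation input, calibration of its shape parameters against activation
# dynamics, total-activation composition, and the continuous stimulated-
# muscle count used to limit treatments to two muscles.

#' Stimulation profile
#'
#' Timing is stored in seconds internally and reported in % gait cycle.
#' Wrap-around stimulation (extending past the end of the cycle into the
#' start) is encoded as `t_off < t_on`.
#'
#' @param amplitude activation-scale amplitude A in `[0, 0.7]`.
#' @param t_on,t_off on/off times (s within `[0, t_end)`).
#' @param t_end gait cycle duration (s).
#' @param c1,c2 rise/fall rate shape parameters (1/s), > 0.
#' @param t_offset1,t_offset2 timing offset shape parameters (s).
#' @return list of class `stimulation_profile`.
#' @export
stimulation_profile <- function(amplitude, t_on, t_off, t_end,
                                c1 = 60, c2 = 40, t_offset1 = 0, t_offset2 = 0) {
  if (amplitude < 0 || amplitude > 0.7)
    stop_gaitfes("stimulation amplitude must be in [0, 0.7]")
  if (c1 <= 0 || c2 <= 0) stop_gaitfes("c1, c2 must be > 0")
  structure(list(amplitude = amplitude, t_on = t_on %% t_end,
                 t_off = t_off %% t_end, t_end = t_end, c1 = c1, c2 = c2,
                 t_offset1 = t_offset1, t_offset2 = t_offset2),
            class = "stimulation_profile")
}

# Core waveform; amplitude/timing passed explicitly so the treatment OCPs can
# differentiate through them. Wrap-around: if t_off < t_on the off time is
# unwrapped into the next cycle and the third (wrap) term reproduces the
# early-cycle portion of the pulse.
stim_wave <- function(t, amplitude, t_on, t_off, t_end, c1, c2,
                      t_offset1 = 0, t_offset2 = 0) {
  wrap <- t_off < t_on
  t_off_u <- t_off + wrap * t_end
  amplitude / 2 * (tanh(c1 * (t - t_on - t_offset1)) -
                   tanh(c2 * (t - t_off_u - t_offset2))) +
    amplitude / 2 * (1 - tanh(c2 * (t - t_off_u - t_offset2 + t_end)))
}

#' Stimulation-induced activation at time t
#'
#' Smooth tanh pulse approximating the activation-dynamics response to a step
#' stimulation of amplitude A between `t_on` and `t_off`, including the
#' wrap-around term that lets stimulation extend past the end of the gait
#' cycle into its start.
#'
#' @param profile a `stimulation_profile`.
#' @param t time (s), vectorized over `[0, t_end]`.
#' @return activation in `[0, A]` (up to tanh junction overshoot).
#' @export
stim_activation <- function(profile, t) {
  stim_wave(t, profile$amplitude, profile$t_on, profile$t_off, profile$t_end,
            profile$c1, profile$c2, profile$t_offset1, profile$t_offset2)
}

#' Calibrate stimulation waveform shape parameters
#'
#' Simulates the muscle's activation dynamics under a unit step excitation on
#' `[t_on, t_off]` over a dense grid, then fits the four shape parameters
#' (`c1`, `c2`, `t_offset1`, `t_offset2`) of the waveform with amplitude 1 by
#' nonlinear least squares.
#'
#' @param params a `muscle_params` (activation time constants used).
#' @param t_on,t_off step on/off times (s); `t_off > t_on` after unwrapping.
#' @param t_end cycle duration (s).
#' @param dt simulation step (s).
#' @return list with `c1`, `c2`, `t_offset1`, `t_offset2`, `rmse`, and
#'   `poor_fit` flag (TRUE when RMSE > 0.05).
#' @export
calibrate_stim_shape <- function(params, t_on, t_off, t_end, dt = 1e-3) {
  t_off_u <- if (t_off > t_on) t_off else t_off + t_end
  if (t_off_u <= t_on) stop_gaitfes("t_off must follow t_on after unwrapping")
  tg <- seq(0, t_end, by = dt)
  u <- as.numeric((tg >= t_on & tg < t_off_u) | (tg + t_end < t_off_u))
  # response without the static nonlinearity: the waveform approximates the
  # linear first-order response, amplitude scaling happens downstream
  p_lin <- params; p_lin$shape <- 0
  # integrate over two cycles so the periodic steady state is reached
  a2 <- activation_dynamics(c(u, u), p_lin, dt, a0 = 0)
  a <- a2[(length(u) + 1):(2 * length(u))]
  resfun <- function(Z) {
    apply(Z, 2, function(z) {
      stim_wave(tg, 1, t_on, t_off %% t_end, t_end, exp(z[1]), exp(z[2]),
                z[3], z[4]) - a
    })
  }
  z0 <- c(log(2 / params$tau_act / 10), log(2 / params$tau_deact / 10), 0.01, 0.02)
  fit <- lm_solve(resfun, z0, max_iter = 200)
  rmse <- sqrt(mean(fit$residual^2))
  list(c1 = exp(fit$z[1]), c2 = exp(fit$z[2]), t_offset1 = fit$z[3],
       t_offset2 = fit$z[4], rmse = rmse, poor_fit = rmse > 0.05)
}

#' Total activation of a stimulated muscle
#'
#' Sum of synergy-generated and stimulation-generated activation. The sum is
#' used as an optimal-control path-constraint quantity (`<= 1`); it is not
#' clamped here.
#'
#' @param a_synergy,a_stim activation series in `[0, 1]`.
#' @return elementwise sum.
#' @export
total_activation <- function(a_synergy, a_stim) a_synergy + a_stim

#' Continuous approximation of the number of stimulated muscles
#'
#' `n = sum_i (1 - exp(-4 A_i))`: each muscle contributes ~0 at zero
#' amplitude and saturates toward 1, giving a differentiable stand-in for a
#' muscle count usable as a terminal constraint (`n <= 2 + tol`).
#'
#' @param amplitudes vector of stimulation amplitudes, >= 0.
#' @return scalar n.
#' @export
effective_muscle_count <- function(amplitudes) {
  if (any(amplitudes < 0)) stop_gaitfes("amplitudes must be >= 0")
  sum(1 - exp(-4 * amplitudes))
}

#' Convert stimulation timing between seconds and % gait cycle
#' @param t_s time in seconds. @param t_end cycle duration (s).
#' @return time in % gait cycle in `[0, 100)`.
#' @export
time_to_percent <- function(t_s, t_end) (t_s %% t_end) / t_end * 100
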