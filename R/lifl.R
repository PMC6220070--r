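#' LIFL neuron parameters
#'
#' Constants of the Leaky Integrate-and-Fire with Latency (LIFL) neuron in its
#' basic configuration: the threshold constant `d`, the linear sub-threshold
#' decay parameter `L_d`, and the absolute refractory period `t_arp`.
#'
#' The internal state `S` is dimensionless and ranges from 0 (rest) upwards.
#' The firing threshold is `S_th = 1 + d`; above it the neuron is *active* and
#' fires after the spike latency `t_f = 1/(S - 1)`, so `d > 0` bounds the
#' maximum latency at `1/d`. Below `S_th` the neuron is *passive* and `S`
#' decays linearly at rate `L_d` (per ms), floored at 0. After firing, `S`
#' stays at 0 and all input is ignored for `t_arp` ms.
#'
#' @param d Threshold constant (dimensionless, > 0). Default 0.04, giving a
#'   maximum latency of 25 ms.
#' @param L_d Decay parameter (1/ms, >= 0). Default 0.37.
#' @param t_arp Absolute refractory period (ms, >= 0). Default 0.
#' @return An object of class `"lifl_params"`: a list with elements `d`,
#'   `L_d`, `t_arp` and the derived threshold `S_th = 1 + d`.
#' @examples
#' p <- lifl_params(d = 0.04)
#' p$S_th            # 1.04
#' max_latency(p$d)  # 25 ms
#' @export
lifl_params <- function(d = 0.04, L_d = 0.37, t_arp = 0) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    mnsd_stop("'d' must be a single positive number")
  if (!is.numeric(L_d) || length(L_d) != 1L || L_d < 0)
    mnsd_stop("'L_d' must be a single non-negative number")
  if (!is.numeric(t_arp) || length(t_arp) != 1L || t_arp < 0)
    mnsd_stop("'t_arp' must be a single non-negative number")
  structure(list(d = d, L_d = L_d, t_arp = t_arp, S_th = 1 + d),
            class = "lifl_params")
}

#' @export
print.lifl_params <- function(x, ...) {
  cat("LIFL neuron parameters\n")
  cat(sprintf("  d     = %g (S_th = %g, t_f,max = %g ms)\n",
              x$d, x$S_th, 1 / x$d))
  cat(sprintf("  L_d   = %g /ms\n", x$L_d))
  cat(sprintf("  t_arp = %g ms\n", x$t_arp))
  invisible(x)
}

#' Sub-threshold leakage over an interval
#'
#' The leakage term `T_l = L_d * dt` removed from the internal state of a
#' passive LIFL neuron between two consecutive input pulses `dt` ms apart.
#'
#' @param L_d Decay parameter (1/ms, >= 0).
#' @param dt Elapsed time (ms, >= 0). Vectorised.
#' @return `L_d * dt` (dimensionless state units).
#' @examples
#' leakage_term(0.37, 1)  # 0.37
#' @export
leakage_term <- function(L_d, dt) {
  if (any(dt < 0)) mnsd_stop("'dt' must be non-negative")
  if (any(L_d < 0)) mnsd_stop("'L_d' must be non-negative")
  L_d * dt
}

#' Spike latency (time-to-fire) of a supra-threshold state
#'
#' The firing equation `t_f = 1/(S - 1)`: the delay between threshold
#' crossing and the actual spike, strictly decreasing in `S`.
#'
#' @param S Internal state (> 1). Vectorised.
#' @return Time-to-fire in ms.
#' @examples
#' firing_equation(1.08)  # 12.5 ms
#' firing_equation(2)     # 1 ms
#' @export
firing_equation <- function(S) {
  if (any(S <= 1)) mnsd_stop("firing equation requires S > 1")
  1 / (S - 1)
}

#' Maximum spike latency
#'
#' The upper bound of the time-to-fire, `t_f,max = 1/d`, attained when the
#' state sits exactly at threshold (`S = S_th = 1 + d`).
#'
#' @param d Threshold constant (> 0). Vectorised.
#' @return `1/d` in ms.
#' @examples
#' max_latency(0.04)  # 25 ms
#' @export
max_latency <- function(d) {
  if (any(d <= 0)) mnsd_stop("'d' must be positive")
  1 / d
}

#' Supra-threshold rise over an interval
#'
#' The rise term `T_r = (S_p - 1)^2 * dt / (1 - (S_p - 1) * dt)` added to the
#' state of an active neuron between two consecutive inputs `dt` ms apart.
#' It is constructed so that the latency countdown is consistent:
#' `firing_equation(S_p + rise_term(S_p, dt)) == firing_equation(S_p) - dt`.
#'
#' @param S_p Previous internal state (> 1, i.e. above threshold).
#' @param dt Elapsed time (ms), with `dt < firing_equation(S_p)`; at larger
#'   `dt` the spike would already have fired and the call is an error.
#' @return The (non-negative) state increment.
#' @examples
#' rise_term(1.5, 1)  # 0.5: latency 2 ms shrinks to 1 ms
#' @export
rise_term <- function(S_p, dt) {
  if (length(S_p) != 1L || length(dt) != 1L)
    mnsd_stop("'S_p' and 'dt' must be scalars")
  if (S_p <= 1) mnsd_stop("rise term requires a supra-threshold state (S_p > 1)")
  if (dt < 0) mnsd_stop("'dt' must be non-negative")
  if (dt >= 1 / (S_p - 1))
    mnsd_stop("'dt' is not smaller than the remaining time-to-fire; the spike should already have fired")
  (S_p - 1)^2 * dt / (1 - (S_p - 1) * dt)
}

# -- single-neuron state machine ---------------------------------------------

#' Resting LIFL neuron state
#'
#' @return A list with elements `S` (0), `mode` (`"passive"`), `t_last`
#'   (`NA`, no prior event), `t_fire` (`NA`, no spike scheduled) and
#'   `t_refr_end`.
#' @export
lifl_rest_state <- function() {
  list(S = 0, mode = "passive", t_last = NA_real_, t_fire = NA_real_,
       t_refr_end = -Inf)
}

# Time comparisons use this tolerance throughout the engine.
.time_tol <- 1e-9

#' Deliver one weighted pulse to a LIFL neuron
#'
#' Applies the passive or active state-update rule. In passive mode the state
#' first decays (`T_l = L_d * dt`, floored at 0), then the pulse amplitude
#' `A * w` is added; if the result reaches the threshold `S_th = 1 + d` the
#' neuron becomes active and a fire is scheduled `firing_equation(S)` ms
#' later. In active mode the rise term accrues before the pulse is added and
#' the pending fire is rescheduled. During the refractory period the pulse is
#' discarded unchanged.
#'
#' A state at exactly `S_th` is treated as active with the maximum latency
#' `1/d`. A pulse arriving exactly when the fire is due drives the state to
#' `Inf` and the fire occurs at the same instant.
#'
#' @param state Neuron state as returned by [lifl_rest_state()] or a previous
#'   call.
#' @param params [lifl_params()].
#' @param time Arrival time of the pulse (ms); must not precede `state$t_last`.
#' @param amplitude Pulse amplitude `A` (> 0).
#' @param weight Synaptic weight `w`.
#' @return The updated state list.
#' @examples
#' st <- lifl_apply_input(lifl_rest_state(), lifl_params(), 0, 1, 1.08)
#' st$t_fire  # 12.5
#' @export
lifl_apply_input <- function(state, params, time, amplitude = 1, weight = 1) {
  if (!is.na(state$t_last) && time < state$t_last - .time_tol)
    mnsd_stop("event time precedes the neuron's last processed event")
  if (state$mode == "refractory") {
    if (time < state$t_refr_end - .time_tol) return(state)  # discarded
    state$S <- 0
    state$mode <- "passive"
    state$t_last <- state$t_refr_end
  }
  dt <- if (is.na(state$t_last)) 0 else max(0, time - state$t_last)
  aw <- amplitude * weight
  if (state$mode == "passive") {
    state$S <- max(0, state$S - params$L_d * dt) + aw
    if (state$S >= params$S_th) {
      state$mode <- "active"
      state$t_fire <- time + firing_equation(state$S)
    }
  } else {  # active
    denom <- 1 - (state$S - 1) * dt
    if (denom <= .time_tol * (state$S - 1)) {
      # pulse lands exactly as the spike is due: fire now
      state$S <- Inf
      state$t_fire <- time
    } else {
      state$S <- state$S + (state$S - 1)^2 * dt / denom + aw
      state$t_fire <- time + 1 / (state$S - 1)
    }
  }
  state$t_last <- time
  state
}

#' Emit the pending spike of an active LIFL neuron
#'
#' Resets the state to 0 and enters the absolute refractory period. The
#' emitted pulse has unit amplitude.
#'
#' @param state Neuron state (must be `"active"`, with `time` equal to the
#'   scheduled fire time).
#' @param params [lifl_params()].
#' @param time Fire time (ms).
#' @return A list with the updated `state` and the emitted `spike`
#'   (`list(time, amplitude = 1)`).
#' @export
lifl_fire <- function(state, params, time) {
  if (state$mode != "active")
    mnsd_stop("fire called on a non-active neuron")
  if (abs(time - state$t_fire) > 1e-6)
    mnsd_stop("fire called at a time other than the scheduled fire time")
  state$S <- 0
  state$t_fire <- NA_real_
  state$t_last <- time
  if (params$t_arp > 0) {
    state$mode <- "refractory"
    state$t_refr_end <- time + params$t_arp
  } else {
    state$mode <- "passive"
    state$t_refr_end <- -Inf
  }
  list(state = state, spike = list(time = time, amplitude = 1))
}
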