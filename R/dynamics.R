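#' Exponential decay of a synaptic current
#'
#' First-order synaptic-current kinetics between spike arrivals:
#' `tau_s dI/dt = -I`, so over a step of length `dt` the current is
#' multiplied by `exp(-dt/tau_s)`. The sign of `I` is preserved, so the same
#' rule serves the excitatory (positive) and inhibitory (negative)
#' accumulators.
#'
#' @param I synaptic current, nA (either sign).
#' @param tau_s synaptic-current time constant, ms (> 0).
#' @param dt elapsed time, ms (> 0).
#' @return Decayed current, nA.
#' @examples
#' decay_current(1, 5, 1)      # exp(-1/5)
#' decay_current(-0.3, 15, 1)
#' @export
decay_current <- function(I, tau_s, dt) {
  if (any(tau_s <= 0)) stop("tau_s must be positive", call. = FALSE)
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  I * exp(-dt / tau_s)
}

#' Deliver arriving spikes into a synaptic-current accumulator
#'
#' Each spike arriving on a synapse of weight w adds w (nA) to the current as
#' a discrete impulse, so a PSC of amplitude w and time constant tau_s
#' carries charge w*tau_s (see [psc_charge()]). All weights delivered to one
#' accumulator share its sign convention.
#'
#' @param I current before delivery, nA.
#' @param incoming_weights numeric vector of synaptic weights (nA) of the
#'   spikes arriving this step; may be empty.
#' @return Updated current `I + sum(incoming_weights)`.
#' @export
add_spike_weights <- function(I, incoming_weights = numeric()) {
  I + sum(incoming_weights)
}

#' Advance the membrane potential under a constant total current
#'
#' Closed-form solution of the LIF membrane equation
#' `tau_m dV/dt = E_L - V + R_m I` over one step with the total synaptic
#' current `I_tot = I_e + I_i` held fixed:
#' `V' = E_L + R_m I_tot + (V - E_L - R_m I_tot) exp(-dt/tau_m)`.
#' Refractory cells stay clamped at `V_reset`; their remaining refractory
#' time decreases by `dt` (floored at 0). Synaptic currents are not modified.
#'
#' This is the constant-current membrane primitive (exact for current-clamp
#' drive). The network engine couples the membrane to the decaying synaptic
#' currents exactly instead; see [advance_neuron()] and the methods vignette.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param dt step length, ms (> 0).
#' @return The advanced `neuron_state`.
#' @export
step_membrane <- function(state, params, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!all(is.finite(c(state$V, state$I_e, state$I_i))))
    stop("numerical failure: non-finite neuron state", call. = FALSE)
  if (state$refrac_remaining > 0) {
    state$V <- params$V_reset
    state$refrac_remaining <- max(0, state$refrac_remaining - dt)
    return(state)
  }
  V_inf <- params$E_L + params$R_m * (state$I_e + state$I_i)
  state$V <- V_inf + (state$V - V_inf) * exp(-dt / params$tau_m)
  state
}

# Coefficient of the exact PSC->membrane convolution over one step:
# contribution of a current I with time constant tau_s to V(t+dt) is
# coef * I, where coef = R_m * tau_s/(tau_s - tau_m) * (e^{-dt/tau_s} -
# e^{-dt/tau_m}); degenerate tau_s == tau_m handled by the limit.
psc_membrane_coef <- function(R_m, tau_s, tau_m, dt) {
  if (abs(tau_s - tau_m) < 1e-9 * tau_m)
    return(R_m * (dt / tau_m) * exp(-dt / tau_m))
  R_m * tau_s / (tau_s - tau_m) * (exp(-dt / tau_s) - exp(-dt / tau_m))
}

#' Advance a neuron state by one step with exact current coupling
#'
#' Propagates the coupled linear system of membrane potential and the two
#' exponentially decaying synaptic currents over one step of length `dt`
#' with its exact (matrix-exponential) solution:
#' `V' = E_L + (V - E_L) e^{-dt/tau_m} + c_e I_e + c_i I_i + R_m I_off (1 - e^{-dt/tau_m})`
#' where `c_s = R_m tau_s/(tau_s - tau_m) (e^{-dt/tau_s} - e^{-dt/tau_m})`,
#' followed by the current decays `I <- I e^{-dt/tau_s}`. This is the update
#' the network engine applies between spike deliveries; it reproduces the
#' continuous-time trajectory of the membrane/synapse equations exactly at
#' the grid points. Refractory handling: the remaining refractory time is
#' decremented first, and the membrane stays clamped at `V_reset` while it is
#' still positive, so a cell that spiked at step t may spike again at step
#' t + t_ref (sustained maximum rate 1000/t_ref Hz). Currents decay during
#' refractoriness; only V is clamped.
#'
#' @inheritParams step_membrane
#' @param I_offset constant injected current, nA (default 0).
#' @return The advanced `neuron_state`.
#' @export
advance_neuron <- function(state, params, dt, I_offset = 0) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!all(is.finite(c(state$V, state$I_e, state$I_i))))
    stop("numerical failure: non-finite neuron state", call. = FALSE)
  em <- exp(-dt / params$tau_m)
  if (state$refrac_remaining > 0)
    state$refrac_remaining <- max(0, state$refrac_remaining - dt)
  if (state$refrac_remaining > 0) {
    state$V <- params$V_reset
  } else {
    ce <- psc_membrane_coef(params$R_m, params$tau_se, params$tau_m, dt)
    ci <- psc_membrane_coef(params$R_m, params$tau_si, params$tau_m, dt)
    state$V <- params$E_L + (state$V - params$E_L) * em +
      ce * state$I_e + ci * state$I_i +
      params$R_m * I_offset * (1 - em)
  }
  state$I_e <- state$I_e * exp(-dt / params$tau_se)
  state$I_i <- state$I_i * exp(-dt / params$tau_si)
  state
}

#' Spike detection and reset
#'
#' Tests a non-refractory neuron against threshold: if `V >= V_theta` the
#' cell spikes, its potential is reset to `V_reset` and its refractory timer
#' is set to `t_ref`; otherwise the state is returned unchanged. The
#' comparison is inclusive, so a membrane exactly at threshold fires.
#'
#' @inheritParams step_membrane
#' @return A list with elements `state` (the possibly reset `neuron_state`)
#'   and `spiked` (logical).
#' @export
threshold_and_reset <- function(state, params) {
  if (state$V >= params$V_theta) {
    state$V <- params$V_reset
    state$refrac_remaining <- params$t_ref
    list(state = state, spiked = TRUE)
  } else {
    list(state = state, spiked = FALSE)
  }
}

#' Charge carried by one exponential postsynaptic current
#'
#' The time integral of a PSC of amplitude `w` (nA) and decay constant
#' `tau_s` (ms) is `w * tau_s` (nA ms = pC). This is the quantity balanced
#' across excitation and inhibition by the extended Brunel condition (see
#' [inhibitory_weight()]).
#'
#' @param w PSC amplitude (synaptic weight), nA.
#' @param tau_s synaptic-current time constant, ms (> 0).
#' @return Charge in pC.
#' @export
psc_charge <- function(w, tau_s) {
  if (any(tau_s <= 0)) stop("tau_s must be positive", call. = FALSE)
  w * tau_s
}
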