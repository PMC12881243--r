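#' Advance a leaky state variable by one update
#'
#' All state variables of the model (membrane potentials, adaptation,
#' firing-rate estimates, global inhibition) obey the same first-order
#' leaky dynamics \eqn{\tau \dot V = -V + k_1 (I + k_2 \eta)}.  The
#' forward-Euler scheme gives
#' `V' = V + (dt/tau) * (-V + k1 * (I + k2 * eta))`; the exact scheme,
#' holding the input constant over the step, gives
#' `V' = V * exp(-dt/tau) + k1 * (I + k2 * eta) * (1 - exp(-dt/tau))`.
#'
#' @param V Current state (vectorised).
#' @param I Input current.
#' @param tau Time constant (> 0), in the same units as `dt`.
#' @param k1 Input gain.
#' @param k2 Noise gain.
#' @param eta Noise sample(s), typically uniform on `[-0.5, 0.5]`.
#' @param dt Step size.
#' @param scheme `"euler"` or `"exact"`.
#' @return Updated state.
#' @export
#' @examples
#' integrate_state(0, 100, tau = 2.5, k1 = 0.01)               # 0.4
#' integrate_state(0, 100, tau = 5, k1 = 0.01, dt = 0.5,
#'                 scheme = "exact")                           # ~0.09516
integrate_state <- function(V, I, tau, k1 = 1, k2 = 0, eta = 0, dt = 1,
                            scheme = c("euler", "exact")) {
  scheme <- match.arg(scheme)
  if (any(tau <= 0)) stop("integrate_state: invalid parameter, tau must be ",
                          "positive")
  a <- if (scheme == "euler") 1 - dt / tau else exp(-dt / tau)
  a * V + (1 - a) * (k1 * (I + k2 * eta))
}

#' Binary spike decision of an excitatory unit
#'
#' A unit emits a spike iff its membrane potential, reduced by the
#' adaptation term `psi * alpha * omega`, strictly exceeds the firing
#' threshold.  The potential reset on spiking (when enabled) is applied by
#' the caller after plasticity has seen the pre-reset potential.
#'
#' @param V Membrane potential(s).
#' @param omega Adaptation state(s) in `[0, 1]`.
#' @param params A [model_parameters()] object (fields `thresh`, `psi`,
#'   `alpha`).
#' @return Integer vector of 0/1 outputs.
#' @export
spike_decision <- function(V, omega, params) {
  as.integer(V - params$psi * params$alpha * omega > params$thresh)
}

#' Leaky low-pass of the spike train: adaptation
#'
#' @param omega Current adaptation state in `[0, 1]`.
#' @param phi Binary spike output (0/1).
#' @param tau_adapt Adaptation time constant.
#' @param dt Step size.
#' @param scheme Integration scheme.
#' @return Updated adaptation, bounded in `[0, 1]`.
#' @export
update_adaptation <- function(omega, phi, tau_adapt, dt = 1,
                              scheme = c("euler", "exact")) {
  integrate_state(omega, phi, tau_adapt, dt = dt, scheme = match.arg(scheme))
}

#' Leaky low-pass of the spike train: firing-rate estimate
#'
#' The estimated instantaneous firing rate drives the presynaptic side of
#' the Hebbian rule; its time constant (30) is slower than adaptation.
#'
#' @param omega_e Current rate estimate in `[0, 1]`.
#' @inheritParams update_adaptation
#' @param tau_favg Rate-estimation time constant.
#' @return Updated rate estimate.
#' @export
update_rate <- function(omega_e, phi, tau_favg = 30, dt = 1,
                        scheme = c("euler", "exact")) {
  integrate_state(omega_e, phi, tau_favg, dt = dt, scheme = match.arg(scheme))
}

#' Leaky integration of the area-wide spike count: global inhibition
#'
#' @param G Current global-inhibition state (scalar per area).
#' @param total_spikes Number of excitatory spikes in the area this step.
#' @param tau_glob Global-inhibition time constant.
#' @inheritParams update_adaptation
#' @return Updated global-inhibition state.
#' @export
update_global <- function(G, total_spikes, tau_glob = 12, dt = 1,
                          scheme = c("euler", "exact")) {
  integrate_state(G, total_spikes, tau_glob, dt = dt,
                  scheme = match.arg(scheme))
}

#' Net synaptic input to a unit
#'
#' Implements the input-current equation
#' \eqn{I = -k_G G + \sum_y w_y \varphi_y + \mathrm{drive}}: uniform
#' global-inhibition feedback plus the strength-scaled weighted sum of
#' delayed presynaptic outputs per synapse class, plus any external drive.
#'
#' @param G Global-inhibition state of the unit's area.
#' @param k_G Global-inhibition gain (0 for units outside its reach).
#' @param synaptic A list of synapse groups, each
#'   `list(strength =, weights =, phi =)` where `weights` and `phi`
#'   (delayed presynaptic outputs) are aligned vectors.
#' @param drive External drive current.
#' @return Net input current (scalar).
#' @export
compute_input <- function(G = 0, k_G = 65, synaptic = list(), drive = 0) {
  syn <- 0
  for (g in synaptic) {
    stopifnot(length(g$weights) == length(g$phi))
    syn <- syn + g$strength * sum(g$weights * g$phi)
  }
  -k_G * G + syn + drive
}

#' Fixed-length ring buffer for delayed synaptic outputs
#'
#' Holds exactly `delay / dt` past values so that an output written at
#' tick `t` is read back at tick `t + delay/dt`, never earlier or later.
#'
#' @param delay Synaptic delay in excitatory-step units.
#' @param dt Tick length in the same units.
#' @param init Initial content (recycled).
#' @param width Number of parallel channels (units) buffered.
#' @return An object of class `ring_buffer` with `$push(x)` (returns the
#'   value falling out, i.e. the output delayed by `delay`) and `$peek()`.
#' @export
ring_buffer <- function(delay, dt = 1, init = 0, width = 1L) {
  len <- delay / dt
  if (abs(len - round(len)) > 1e-9 || len < 1)
    stop("ring_buffer: delay must be a positive multiple of dt")
  len <- as.integer(round(len))
  buf <- matrix(init, nrow = len, ncol = width)
  pos <- 0L
  push <- function(x) {
    pos <<- (pos %% len) + 1L
    out <- buf[pos, ]
    buf[pos, ] <<- x
    out
  }
  peek <- function() buf[(pos %% len) + 1L, ]
  structure(list(push = push, peek = peek, length = len),
            class = "ring_buffer")
}
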