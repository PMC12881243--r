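#' Synapse class constants
#'
#' Single source for the per-class strength multipliers and delays
#' (excitatory-step units): excitatory-to-excitatory 500 (delay 1),
#' inhibitory-to-excitatory 1500, excitatory-to-global 1,
#' global-to-excitatory 65, excitatory-to-inhibitory kernel-weighted with
#' unit strength (all delay 0.5).
#'
#' @return Named list of `list(strength, delay)` per synapse class.
#' @export
synapse_class_defaults <- function() {
  list(
    EE_local   = list(strength = 500,  delay = 1),
    EE_between = list(strength = 500,  delay = 1),
    EI         = list(strength = 1,    delay = 0.5),
    IE         = list(strength = 1500, delay = 0.5),
    E_GI       = list(strength = 1,    delay = 0.5),
    GI_E       = list(strength = 65,   delay = 0.5))
}

#' Neuron and integration parameters
#'
#' Builds the full parameter set for the two numerical backends.  The
#' `"felix"` preset uses synchronous forward-Euler updating at resolution
#' `dt = 1` excitatory step, with membrane time constants 2.5 / 5 / 12
#' steps for excitatory, inhibitory and global-inhibitory units,
#' adaptation constant 10 and firing-rate constant 30.  The `"nest"`
#' preset uses exact integration on a half-step grid (`dt = 0.5`) with
#' explicit synaptic delays; its time constants (5 / 10 / 24, adaptation
#' 20, firing-rate 30) are expressed in half-step units, so membrane and
#' adaptation constants correspond to the same real time as the felix
#' column.  Both columns share the input gains (`k1` 0.01 / 1 / 1), noise
#' gains (`k2` 0.005 / 0 / 0), firing threshold 0.18 and the adaptation
#' scaling factor `psi = 0.872`.
#'
#' The adaptation gain `alpha` is not fixed by the model tables; it enters
#' only through the product `psi * alpha` and defaults to 1.
#'
#' @param preset `"felix"` or `"nest"`.
#' @param ... Named overrides for any field.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(preset = c("felix", "nest"), ...) {
  preset <- match.arg(preset)
  cls <- synapse_class_defaults()
  base <- list(
    preset = preset,
    k1_exc = 0.01, k1_inh = 1, k1_glob = 1,
    k2_exc = 0.005, k2_inh = 0, k2_glob = 0,
    thresh = 0.18, psi = 0.872, alpha = 1,
    k_G = cls$GI_E$strength,
    strength_ee = cls$EE_local$strength,
    strength_ei = cls$EI$strength,
    strength_ie = cls$IE$strength,
    strength_egi = cls$E_GI$strength,
    spike_reset = TRUE)
  if (preset == "felix") {
    base <- c(base, list(
      mode = "felix", dt = 1, scheme = "euler",
      tau_exc = 2.5, tau_inh = 5, tau_glob = 12,
      tau_adapt = 10, tau_favg = 30))
  } else {
    base <- c(base, list(
      mode = "delay", dt = 0.5, scheme = "exact",
      tau_exc = 5, tau_inh = 10, tau_glob = 24,
      tau_adapt = 20, tau_favg = 30))
  }
  over <- list(...)
  unknown <- setdiff(names(over), c(names(base)))
  if (length(unknown))
    stop("model_parameters: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  base[names(over)] <- over
  p <- structure(base, class = "model_parameters")
  validate_model_parameters(p)
  p
}

validate_model_parameters <- function(p) {
  taus <- c(p$tau_exc, p$tau_inh, p$tau_glob, p$tau_adapt, p$tau_favg)
  if (any(taus <= 0)) stop("model_parameters: invalid parameter, all time ",
                           "constants must be positive")
  if (p$dt <= 0) stop("model_parameters: dt must be positive")
  if (p$thresh <= 0) stop("model_parameters: thresh must be positive")
  if (p$mode == "felix" && p$dt != 1)
    stop("model_parameters: felix mode requires dt = 1")
  if (p$mode == "delay" && p$dt != 0.5)
    stop("model_parameters: delay mode requires dt = 0.5")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("model_parameters [%s]: mode=%s dt=%g scheme=%s\n",
              x$preset, x$mode, x$dt, x$scheme))
  cat(sprintf("  tau: exc=%g inh=%g glob=%g adapt=%g favg=%g (%s units)\n",
              x$tau_exc, x$tau_inh, x$tau_glob, x$tau_adapt, x$tau_favg,
              if (x$mode == "felix") "step" else "half-step"))
  cat(sprintf("  thresh=%g psi=%g alpha=%g k_G=%g spike_reset=%s\n",
              x$thresh, x$psi, x$alpha, x$k_G, x$spike_reset))
  invisible(x)
}

#' Per-update decay factors for each population
#'
#' Every population advances once per excitatory step.  In felix mode the
#' forward-Euler update gives decay factor `1 - dt/tau`; in delay mode the
#' exact-integration update over one full step (two half-step ticks, with
#' time constants stated in half-step units) gives `exp(-2 * dt / tau)`.
#' In both cases the state update is
#' `V' = a * V + (1 - a) * k1 * (I + k2 * eta)`.
#'
#' @param p A [model_parameters()] object.
#' @return Named list of decay factors `exc`, `inh`, `glob`, `adapt`,
#'   `favg`.
#' @keywords internal
decay_factors <- function(p) {
  taus <- c(exc = p$tau_exc, inh = p$tau_inh, glob = p$tau_glob,
            adapt = p$tau_adapt, favg = p$tau_favg)
  if (p$mode == "felix") {
    a <- 1 - 1 / taus
  } else {
    a <- exp(-1 / (taus * p$dt))  # interval = 1 step = (1/dt) ticks
  }
  as.list(a)
}

#' Mode-matched time constant for the exact-integration backend
#'
#' Returns the time constant (in the delay backend's half-step units) for
#' which one exact-integration update over a full excitatory step has the
#' same decay factor as one forward-Euler step with time constant
#' `tau_felix`: `exp(-1/tau') = 1 - 1/tau_felix`.  Running the delay
#' backend with matched constants makes the two backends algebraically
#' identical maps, which is the basis of the backend-equivalence checks.
#'
#' @param tau_felix Felix-mode time constant in excitatory-step units
#'   (must exceed 1 so the Euler factor is positive).
#' @param dt Delay-mode resolution (default 0.5).
#' @return Matched time constant in units of `dt`.
#' @export
matched_tau <- function(tau_felix, dt = 0.5) {
  if (any(tau_felix <= 1))
    stop("matched_tau: tau_felix must exceed 1 step")
  (-1 / log(1 - 1 / tau_felix)) / dt
}

#' Delay-mode parameters matched to a felix-mode parameter set
#'
#' @param felix A felix-mode [model_parameters()] object.
#' @return A delay-mode `model_parameters` object whose decay factors
#'   equal those of `felix` exactly.
#' @export
matched_parameters <- function(felix) {
  stopifnot(inherits(felix, "model_parameters"), felix$mode == "felix")
  model_parameters(
    "nest",
    tau_exc = matched_tau(felix$tau_exc),
    tau_inh = matched_tau(felix$tau_inh),
    tau_glob = matched_tau(felix$tau_glob),
    tau_adapt = matched_tau(felix$tau_adapt),
    tau_favg = matched_tau(felix$tau_favg),
    thresh = felix$thresh, psi = felix$psi, alpha = felix$alpha,
    spike_reset = felix$spike_reset,
    k2_exc = felix$k2_exc)
}

#' ABS plasticity parameters
#'
#' Thresholds and step size of the discretised
#' Artola-Broecher-Singer rule.  Both presets share the presynaptic rate
#' threshold `theta_pre = 0.05`, the upper postsynaptic threshold
#' `theta_plus = 0.15` and the weight ceiling `w_max = 0.225`; the felix
#' preset uses `theta_minus = 0.14` with step `delta = 8e-4`, the nest
#' preset `theta_minus = 0.11` with `delta = 2e-4`.
#'
#' @param preset `"felix"` or `"nest"`.
#' @param ... Named overrides.
#' @return An object of class `plasticity_parameters`.
#' @export
plasticity_parameters <- function(preset = c("felix", "nest"), ...) {
  preset <- match.arg(preset)
  p <- list(preset = preset,
            theta_pre = 0.05, theta_plus = 0.15,
            theta_minus = if (preset == "felix") 0.14 else 0.11,
            delta = if (preset == "felix") 8e-4 else 2e-4,
            w_max = 0.225, w_min = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("plasticity_parameters: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (p$theta_minus > p$theta_plus || p$theta_minus < 0)
    stop("plasticity_parameters: need 0 <= theta_minus <= theta_plus")
  if (p$delta <= 0) stop("plasticity_parameters: delta must be positive")
  if (p$w_min >= p$w_max)
    stop("plasticity_parameters: w_min must be below w_max")
  structure(p, class = "plasticity_parameters")
}
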