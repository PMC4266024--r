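#' Neuron state container
#'
#' Holds the dynamical variables of a population of conductance-based leaky
#' integrate-and-fire neurons: membrane potential \code{V} (mV), summed
#' excitatory and inhibitory conductances (dimensionless weight units), the
#' spike flag of the current step, and each neuron's last spike time (ms,
#' \code{-Inf} for never).
#'
#' @param n number of neurons.
#' @param cfg an \code{\link{snn_config}}; membrane potentials start at
#'   \code{V_rest}.
#' @return an object of class \code{snn_neurons}.
#' @export
neuron_state <- function(n, cfg) {
  stopifnot(n >= 1)
  structure(list(V = rep(cfg$V_rest, n), g_ex = numeric(n), g_inh = numeric(n),
                 spiked_now = logical(n), last_spike_time = rep(-Inf, n)),
            class = "snn_neurons")
}

#' One Euler step of the membrane equation
#'
#' Advances \code{tau_m dV/dt = (V_rest - V) + (E_ex - V) g_ex / g_leak +
#' (E_inh - V) g_inh / g_leak} by one explicit Euler step of length
#' \code{dt}; conductances enter in units of the leak conductance
#' \code{g_leak} (see \code{\link{snn_config}}).
#' Neurons reaching threshold (\code{V >= V_T}, the equality fires) emit a
#' spike, are reset to \code{V_reset}, and have their last spike time set to
#' \code{t_now}.  There is no refractory period.
#'
#' @param state an \code{\link{neuron_state}} with conductances already
#'   updated for this step.
#' @param cfg an \code{\link{snn_config}}.
#' @param t_now current time in ms (recorded as the spike time).
#' @return the advanced \code{snn_neurons} state.
#' @export
step_membrane <- function(state, cfg, t_now = 0) {
  stopifnot(inherits(state, "snn_neurons"))
  v <- state$V +
    cfg$dt / cfg$tau_m * ((cfg$V_rest - state$V) +
                          (cfg$E_ex - state$V) * (state$g_ex / cfg$g_leak) +
                          (cfg$E_inh - state$V) * (state$g_inh / cfg$g_leak_gaba))
  if (any(!is.finite(v)))
    stop("non-finite membrane potential: parameter blow-up")
  sp <- v >= cfg$V_T | state$V >= cfg$V_T
  v[sp] <- cfg$V_reset
  state$V <- v
  state$spiked_now <- sp
  state$last_spike_time[sp] <- t_now
  state
}

#' One step of the conductance dynamics
#'
#' Decays both conductances (explicit Euler \code{g <- g (1 - dt/tau)} by
#' default, exact exponential when \code{cfg$exact_decay}) and adds the
#' summed weights of synapses whose presynaptic neuron spiked this step
#' (delta-pulse input).
#'
#' @param state an \code{\link{neuron_state}}.
#' @param incoming_ex,incoming_inh per-neuron sums of excitatory /
#'   inhibitory synaptic weights with a presynaptic spike this step.
#' @param cfg an \code{\link{snn_config}}.
#' @return the updated \code{snn_neurons} state.
#' @export
step_conductances <- function(state, incoming_ex, incoming_inh, cfg) {
  stopifnot(inherits(state, "snn_neurons"),
            length(incoming_ex) == length(state$g_ex),
            length(incoming_inh) == length(state$g_inh))
  if (any(incoming_ex < 0) || any(incoming_inh < 0))
    stop("negative synaptic weight sums")
  dE <- if (cfg$exact_decay) exp(-cfg$dt / cfg$tau_AMPA) else 1 - cfg$dt / cfg$tau_AMPA
  dI <- if (cfg$exact_decay) exp(-cfg$dt / cfg$tau_GABA) else 1 - cfg$dt / cfg$tau_GABA
  state$g_ex <- state$g_ex * dE + incoming_ex
  state$g_inh <- state$g_inh * dI + incoming_inh
  state
}

#' Synaptic currents at the current state
#'
#' Returns the excitatory driving current \code{(E_ex - V) g_ex / g_leak},
#' the inhibitory current \code{(E_inh - V) g_inh / g_leak}, and their sum
#' (in mV, i.e. driving force times conductance in leak units).  In the
#' balanced regime the net current hovers near zero while both components
#' are large; the balance diagnostics of the experiment drivers are built on
#' these quantities.
#'
#' @param state an \code{\link{neuron_state}}.
#' @param cfg an \code{\link{snn_config}}.
#' @return a list with per-neuron vectors \code{I_ex}, \code{I_inh},
#'   \code{I_net} (mV x weight units).
#' @export
net_currents <- function(state, cfg) {
  stopifnot(inherits(state, "snn_neurons"))
  I_ex <- (cfg$E_ex - state$V) * (state$g_ex / cfg$g_leak)
  I_inh <- (cfg$E_inh - state$V) * (state$g_inh / cfg$g_leak_gaba)
  list(I_ex = I_ex, I_inh = I_inh, I_net = I_ex + I_inh)
}
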