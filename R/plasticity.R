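#' Excitatory STDP weight change
#'
#' Anti-symmetric additive STDP for excitatory synapses (E->E and E->I).
#' With \code{delta_t = t_pre - t_post}, a presynaptic spike preceding the
#' postsynaptic spike (\code{delta_t < 0}) potentiates by
#' \code{A_plus * exp(delta_t / tau_plus)}; otherwise the synapse is
#' depressed by \code{A_minus * exp(-delta_t / tau_minus)}, where
#' \code{A_minus = beta * A_plus * tau_plus / tau_minus} carries a slight
#' depression bias at the default \code{beta = 1.05}.
#'
#' @param delta_t spike-timing difference t_pre - t_post in ms (vectorized).
#' @param cfg an \code{\link{snn_config}}.
#' @return weight increment(s), same length as \code{delta_t}.
#' @examples
#' cfg <- snn_config()
#' estdp_delta(-10, cfg)   # causal pair: potentiation
#' estdp_delta(0, cfg)     # simultaneous: -A_minus
#' @export
estdp_delta <- function(delta_t, cfg) {
  stopifnot(all(is.finite(delta_t)))
  ifelse(delta_t < 0,
         cfg$A_plus * exp(delta_t / cfg$tau_plus),
         -cfg$A_minus * exp(-delta_t / cfg$tau_minus))
}

#' Inhibitory STDP weight change
#'
#' Symmetric STDP for inhibitory synapses (I->E and I->I): near-coincident
#' pre/post spikes (\code{|delta_t| <= tau_i}) potentiate regardless of
#' order, distal pairs depress; both branches decay as
#' \code{exp(-|delta_t| / tau_i)}.
#'
#' @inheritParams estdp_delta
#' @return weight increment(s).
#' @export
istdp_delta <- function(delta_t, cfg) {
  stopifnot(all(is.finite(delta_t)))
  a <- abs(delta_t)
  ifelse(a <= cfg$tau_i,
         cfg$B_plus * exp(-a / cfg$tau_i),
         -cfg$B_minus * exp(-a / cfg$tau_i))
}

#' Classify the joint E/I plasticity regime of a spike pair
#'
#' The interplay of the two rules partitions the timing axis into four
#' regimes by causality (sign of \code{delta_t}) and proximity
#' (\code{|delta_t|} vs \code{tau_i}): proximal causal pairs increase both
#' conductances ("balance"), distal causal pairs potentiate excitation while
#' inhibition decays ("accelerated potentiation"), distal anti-causal pairs
#' weaken both ("decelerated depression"), and proximal anti-causal pairs
#' strongly depress excitation while inhibition grows ("quiescent").
#'
#' @inheritParams estdp_delta
#' @return character vector of regime tags.
#' @export
classify_regime <- function(delta_t, cfg) {
  stopifnot(all(is.finite(delta_t)))
  causal <- delta_t < 0
  proximal <- abs(delta_t) <= cfg$tau_i
  ifelse(causal,
         ifelse(proximal, "balance", "accelerated_potentiation"),
         ifelse(proximal, "quiescent", "decelerated_depression"))
}

#' Construct a synapse-class matrix
#'
#' One realized projection: a fixed boolean connectivity mask and a weight
#' matrix (pre x post), clipped to \code{[0, g_max]}.  Weights are zero
#' wherever the mask is \code{FALSE}; the mask never changes after
#' construction (no structural plasticity).
#'
#' @param mask logical pre x post connectivity matrix.
#' @param weights numeric matrix of the same shape.
#' @param class_tag one of \code{"E->E"}, \code{"E->I"}, \code{"I->E"},
#'   \code{"I->I"}.
#' @param g_max upper clip bound for this class.
#' @return an object of class \code{snn_synapses}.
#' @export
synapse_matrix <- function(mask, weights, class_tag = c("E->E", "E->I", "I->E", "I->I"),
                           g_max) {
  class_tag <- match.arg(class_tag)
  stopifnot(is.matrix(mask), is.matrix(weights), all(dim(mask) == dim(weights)),
            g_max > 0)
  mask <- mask != 0
  weights[!mask] <- 0
  if (any(weights < 0) || any(weights > g_max))
    stop("weights outside [0, g_max]")
  structure(list(mask = mask, weights = weights, class_tag = class_tag,
                 g_max = g_max, excitatory = class_tag %in% c("E->E", "E->I")),
            class = "snn_synapses")
}

#' Apply one STDP update step to a synapse-class matrix
#'
#' Reference (pure R) implementation of the per-step plasticity update used
#' inside the simulation loop: for every postsynaptic neuron that spiked
#' this step, each incoming synapse is updated against the presynaptic
#' neuron's stored last spike time (\code{delta_t = last_pre - t_now < 0});
#' for every presynaptic neuron that spiked, each outgoing synapse is
#' updated against the postsynaptic last spike
#' (\code{delta_t = t_now - last_post >= 0}).  Excitatory classes use
#' \code{\link{estdp_delta}}, inhibitory classes \code{\link{istdp_delta}};
#' results are clipped to \code{[0, g_max]}.  Nearest-neighbour pairing:
#' only the single stored last spike per neuron enters the update.
#'
#' @param syn an \code{\link{synapse_matrix}} object.
#' @param pre_spikes,post_spikes logical vectors: which neurons spiked this
#'   step.
#' @param last_pre,last_post last spike times (ms) per neuron, excluding the
#'   current step (\code{-Inf} for never).
#' @param t_now current time in ms.
#' @param cfg an \code{\link{snn_config}}.
#' @param depression_amp depression amplitude for excitatory classes;
#'   defaults to \code{cfg$A_minus}, the purely feed-forward classes use
#'   \code{cfg$A_minus_readout}.
#' @return the updated \code{snn_synapses} object.
#' @export
apply_stdp <- function(syn, pre_spikes, post_spikes, last_pre, last_post, t_now, cfg,
                       depression_amp = cfg$A_minus) {
  stopifnot(inherits(syn, "snn_synapses"),
            length(pre_spikes) == nrow(syn$weights),
            length(post_spikes) == ncol(syn$weights),
            length(last_pre) == length(pre_spikes),
            length(last_post) == length(post_spikes))
  f <- if (syn$excitatory) {
    function(dt, cfg) ifelse(dt < 0, cfg$A_plus * exp(dt / cfg$tau_plus),
                             -depression_amp * exp(-dt / cfg$tau_minus))
  } else istdp_delta
  W <- syn$weights
  # post spikes: potentiation-side pairing with pre's last spike
  for (j in which(post_spikes)) {
    idx <- syn$mask[, j]
    dtp <- last_pre[idx] - t_now
    dw <- ifelse(is.finite(dtp), f(pmax(dtp, -1e6), cfg), 0)
    W[idx, j] <- pmin(pmax(W[idx, j] + dw, 0), syn$g_max)
  }
  # pre spikes: depression-side pairing with post's last spike
  for (i in which(pre_spikes)) {
    idx <- syn$mask[i, ]
    dtp <- t_now - last_post[idx]
    dw <- ifelse(is.finite(dtp), f(pmin(dtp, 1e6), cfg), 0)
    W[i, idx] <- pmin(pmax(W[i, idx] + dw, 0), syn$g_max)
  }
  syn$weights <- W
  syn
}
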