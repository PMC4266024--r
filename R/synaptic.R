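#' Binarize a weight matrix at the strong-synapse threshold
#'
#' A synapse is "strong" when its weight exceeds \code{0.7 * g_max} for its
#' class; under the additive excitatory STDP rule trained weights are
#' bimodal, so this binarization captures the receptive-field structure.
#'
#' @param syn an \code{\link{synapse_matrix}} object, or a plain numeric
#'   matrix together with \code{g_max}.
#' @param g_max clip bound (taken from \code{syn} when omitted).
#' @param threshold fraction of \code{g_max} (default 0.7).
#' @return binary 0/1 matrix of the same shape.
#' @export
binarize_weights <- function(syn, g_max = NULL, threshold = 0.7) {
  if (inherits(syn, "snn_synapses")) {
    W <- syn$weights
    if (is.null(g_max)) g_max <- syn$g_max
  } else W <- syn
  stopifnot(is.matrix(W), is.numeric(g_max))
  (W > threshold * g_max) + 0
}

#' Synaptic distance between two binary weight snapshots
#'
#' Normalized Hamming distance: the fraction of the \code{#k * #l}
#' pre-post pairs whose strong/weak state differs between the two times.
#'
#' @param snap1,snap2 binary matrices of identical shape (see
#'   \code{\link{binarize_weights}}).
#' @return scalar distance in [0, 1].
#' @export
synaptic_distance <- function(snap1, snap2) {
  stopifnot(is.matrix(snap1), is.matrix(snap2))
  if (!all(dim(snap1) == dim(snap2))) stop("snapshot shape mismatch")
  mean(abs(snap2 - snap1))
}

#' Chance-level synaptic distance via entry shuffles
#'
#' Mean Hamming distance between the first snapshot and independent uniform
#' permutations of the second snapshot's entries.  The permutation
#' preserves the number of strong synapses (the density), so the result
#' estimates the distance expected if the second snapshot's strong synapses
#' had formed by chance: for densities p1, p2 the expectation is
#' \code{p1 (1 - p2) + p2 (1 - p1)}.
#'
#' @param snap1,snap2 binary matrices of identical shape.
#' @param n_shuffles number of independent permutations (default 10).
#' @param seed optional RNG seed.
#' @return scalar mean shuffled distance.
#' @export
shuffled_distance <- function(snap1, snap2, n_shuffles = 10, seed = NULL) {
  stopifnot(is.matrix(snap1), is.matrix(snap2))
  if (!all(dim(snap1) == dim(snap2))) stop("snapshot shape mismatch")
  with_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(k) {
      shuf <- matrix(sample(as.vector(snap2)), nrow(snap2))
      synaptic_distance(snap1, shuf)
    }, 0))
  })
}

#' Relative synaptic distance
#'
#' \code{|phi - phi_shuffled| / phi_shuffled}: how far the observed
#' synaptic change is from chance-level change.  Values near 1 indicate
#' either essentially no change (phi near 0) relative to chance, i.e.
#' stabilized learning.  Undefined (returns \code{NA}) when
#' \code{phi_shuffled = 0}, which occurs when the binarized weights carry
#' no strong synapses or the comparison is degenerate.
#'
#' @param phi observed synaptic distance.
#' @param phi_shuffled chance-level distance.
#' @return scalar, or \code{NA} when undefined.
#' @export
relative_distance <- function(phi, phi_shuffled) {
  stopifnot(phi >= 0, phi_shuffled >= 0)
  if (phi_shuffled == 0) return(NA_real_)
  abs(phi - phi_shuffled) / phi_shuffled
}

#' Receptive field of a reservoir neuron
#'
#' Reshapes the incoming source->reservoir weight vector of one reservoir E
#' neuron back into image coordinates (row-major, matching the encoder's
#' flattening) and marks strong synapses.
#'
#' @param net an \code{snn_network}.
#' @param neuron_id reservoir E neuron index (1..N_E).
#' @param threshold strong-synapse threshold as a fraction of gE_max.
#' @return a list with \code{weights} (image-shaped matrix) and
#'   \code{strong} (logical matrix).
#' @export
receptive_field <- function(net, neuron_id, threshold = 0.7) {
  stopifnot(inherits(net, "snn_network"))
  if (neuron_id < 1 || neuron_id > net$cfg$N_E) stop("neuron id out of range")
  w <- net$proj$w12$weights[, neuron_id]
  s <- net$cfg$image_size
  field <- matrix(w, s, s, byrow = TRUE)   # inverse of row-major flattening
  list(weights = field, strong = field > threshold * net$cfg$gE_max)
}

#' Strong-synapse fraction of a projection
#'
#' Fraction of realized synapses above \code{threshold * g_max}.
#'
#' @param net an \code{snn_network}.
#' @param projection projection name (default \code{"w12"}).
#' @param threshold fraction of the class g_max.
#' @return scalar fraction in [0, 1].
#' @export
strong_fraction <- function(net, projection = "w12", threshold = 0.7) {
  syn <- net$proj[[projection]]
  if (is.null(syn)) stop("unknown projection: ", projection)
  mean(syn$weights[syn$mask] > threshold * syn$g_max)
}

#' Structural and functional back-trace graphs
#'
#' Traces the sub-network behind a pattern's readout: the readout neurons
#' carrying the top code symbol during the presentation are selected; the
#' structural graph contains the reservoir E neurons strongly connected
#' (weight > \code{threshold * gE_max}) to those readout neurons, plus the
#' strong E->E edges among them.  The functional graph, on the same node
#' set, weights each directed edge (a, b) by the number of times b spiked
#' within one STDP window (\code{window_ms}, default \code{tau_plus}) after
#' a during the presentation; it is typically far sparser than the
#' structural graph.
#'
#' @param net a trained \code{snn_network}.
#' @param spikes spike record of a test presentation (data frame
#'   \code{layer, neuron_id, time_ms} from \code{\link{run_network}} with
#'   \code{record = "network"}).
#' @param code the readout symbol vector of the presentation (length M).
#' @param threshold strong-synapse threshold fraction.
#' @param window_ms transition window in ms (default \code{tau_plus}).
#' @return list of two \code{igraph} objects, \code{structural} and
#'   \code{functional}.
#' @export
backtrace_networks <- function(net, spikes, code, threshold = 0.7,
                               window_ms = net$cfg$tau_plus) {
  stopifnot(inherits(net, "snn_network"), length(code) == net$cfg$M)
  top <- which(code == max(code) & code > 0)
  W23 <- net$proj$w23$weights
  strong23 <- W23 > threshold * net$cfg$gE_max
  nodes <- if (length(top)) which(rowSums(strong23[, top, drop = FALSE]) > 0) else integer(0)
  W22 <- net$proj$w22ee$weights
  strong22 <- W22 > threshold * net$cfg$gE_max
  edges <- which(strong22[nodes, nodes, drop = FALSE], arr.ind = TRUE)
  struct_el <- if (nrow(edges)) data.frame(src = nodes[edges[, 1]],
                                           dst = nodes[edges[, 2]],
                                           weight = W22[cbind(nodes[edges[, 1]],
                                                              nodes[edges[, 2]])])
               else data.frame(src = integer(0), dst = integer(0), weight = numeric(0))
  g_struct <- igraph::graph_from_data_frame(
    struct_el, directed = TRUE,
    vertices = data.frame(name = as.character(nodes)))

  res_sp <- spikes[spikes$layer == "reservoir_E" & spikes$neuron_id %in% nodes, ]
  res_sp <- res_sp[order(res_sp$time_ms), ]
  func_counts <- new.env(parent = emptyenv())
  if (nrow(res_sp) > 1) {
    tm <- res_sp$time_ms; id <- res_sp$neuron_id
    j0 <- 1
    for (a in seq_len(nrow(res_sp) - 1)) {
      b <- a + 1
      while (b <= nrow(res_sp) && tm[b] - tm[a] <= window_ms) {
        if (id[b] != id[a] && tm[b] > tm[a]) {
          key <- paste(id[a], id[b])
          func_counts[[key]] <- (if (is.null(func_counts[[key]])) 0 else func_counts[[key]]) + 1
        }
        b <- b + 1
      }
    }
  }
  keys <- ls(func_counts)
  func_el <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, " "))
    data.frame(src = as.integer(parts[, 1]), dst = as.integer(parts[, 2]),
               weight = vapply(keys, function(k) func_counts[[k]], 0))
  } else data.frame(src = integer(0), dst = integer(0), weight = numeric(0))
  g_func <- igraph::graph_from_data_frame(
    func_el, directed = TRUE,
    vertices = data.frame(name = as.character(nodes)))
  list(structural = g_struct, functional = g_func)
}

#' Export a back-trace graph
#'
#' Writes an edge-list CSV (\code{src,dst,weight}) and, optionally, GraphML.
#'
#' @param graph an \code{igraph} object from
#'   \code{\link{backtrace_networks}}.
#' @param path CSV path.
#' @param graphml_path optional GraphML path.
#' @export
write_graph_csv <- function(graph, path, graphml_path = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("src", "dst")
  utils::write.csv(el, path, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  invisible(path)
}
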