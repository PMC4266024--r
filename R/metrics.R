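#' Banded firing-rate code of the readout layer
#'
#' Converts the spike counts of the M readout neurons over one test window
#' into a symbol vector over \code{{0, ..., C-1}}.  Each neuron's count is
#' divided by the maximal count across neurons and the ratio is banded: for
#' the ternary default, symbol 2 for ratios in [0.9, 1], 1 for [0.4, 0.9),
#' 0 below 0.4.  The top band includes the ratio 1 so the maximal neuron
#' always carries the top symbol; all-zero counts yield the all-zero code.
#'
#' For other coding levels the default bands are: binary, threshold 0.5;
#' \code{C > 3}, a fixed top band at 0.9 with the interior split into
#' \code{C - 1} equal bands.  \code{edges} overrides the band boundaries
#' (length \code{C - 1}, increasing).
#'
#' @param counts non-negative spike counts, one per readout neuron.
#' @param C coding level (number of symbols, >= 2).
#' @param edges optional band boundaries on the rate ratio.
#' @return integer symbol vector of the same length as \code{counts}.
#' @examples
#' rate_code(c(40, 36, 16, 4), C = 3)   # 2 2 1 0
#' @export
rate_code <- function(counts, C = 3, edges = NULL) {
  stopifnot(all(counts >= 0), C >= 2)
  if (is.null(edges)) edges <- default_band_edges(C)
  stopifnot(length(edges) == C - 1, !is.unsorted(edges))
  fmax <- max(counts)
  if (fmax == 0) return(integer(length(counts)))
  findInterval(counts / fmax, edges)
}

default_band_edges <- function(C) {
  if (C == 2) 0.5
  else if (C == 3) c(0.4, 0.9)
  else c(0.9 * seq_len(C - 2) / (C - 1), 0.9)
}

#' Prototype (modal) code across repeated presentations
#'
#' The most frequent code among the \code{J} codes observed for one
#' pattern; ties, and the case where no code repeats, are broken uniformly
#' at random.
#'
#' @param codes a \code{J x M} matrix of symbols (one row per repeat).
#' @return the prototype symbol vector (length M).
#' @export
prototype_code <- function(codes) {
  stopifnot(is.matrix(codes), nrow(codes) >= 1)
  key <- apply(codes, 1, paste, collapse = ",")
  tab <- table(key)
  top <- names(tab)[tab == max(tab)]
  pick <- if (length(top) == 1) top else sample(top, 1)
  codes[match(pick, key), ]
}

#' Inter-pattern distance between prototype codes
#'
#' For every unordered pair of patterns and every readout neuron, symbols
#' disagree (1) or agree (0); the per-neuron distance is the mean
#' disagreement over all \code{P(P-1)/2} pairs, and the total inter-pattern
#' distance is its sum over the M neurons.
#'
#' @param prototypes a \code{P x M} matrix of prototype symbols.
#' @return list with \code{D_inter} (scalar) and \code{per_neuron}
#'   (length-M vector).
#' @export
inter_pattern_distance <- function(prototypes) {
  stopifnot(is.matrix(prototypes))
  P <- nrow(prototypes)
  if (P < 2) stop("need at least two patterns")
  pairs <- utils::combn(P, 2)
  disag <- matrix(0, ncol(pairs), ncol(prototypes))
  for (k in seq_len(ncol(pairs)))
    disag[k, ] <- prototypes[pairs[1, k], ] != prototypes[pairs[2, k], ]
  per_neuron <- colMeans(disag)
  list(D_inter = sum(per_neuron), per_neuron = per_neuron)
}

#' Intra-pattern distance across repeats
#'
#' Average pairwise code distance (summed over neurons, as in the
#' inter-pattern distance) over all unique pairs of the \code{J} repeats of
#' one pattern, averaged (unweighted) over patterns.
#'
#' @param codes_by_pattern list (one element per pattern) of \code{J x M}
#'   symbol matrices.
#' @return scalar \code{D_intra}.
#' @export
intra_pattern_distance <- function(codes_by_pattern) {
  per_pattern <- vapply(codes_by_pattern, function(codes) {
    J <- nrow(codes)
    if (J < 2) stop("need at least two repeats per pattern")
    pairs <- utils::combn(J, 2)
    mean(vapply(seq_len(ncol(pairs)),
                function(k) sum(codes[pairs[1, k], ] != codes[pairs[2, k], ]),
                0))
  }, 0)
  mean(per_pattern)
}

#' Theoretical maximum of the inter-pattern distance
#'
#' Upper bound on \code{D_inter} for \code{P} patterns, coding level
#' \code{C} and \code{M} readout neurons, attained when symbols are spread
#' as evenly as possible across patterns at every neuron.
#'
#' Two methods are provided.  \code{"printed"} (default) evaluates the
#' parity-cased closed form of the source derivation, whose worked value at
#' \code{P = 15, C = 2, M = 8} is 4.2857 (printed as 4.28): per neuron,
#' \code{P(C-1)/(C(P-1))} for odd \code{P} and \code{(P+1)(C-1)/(CP)} for
#' even \code{P}.  \code{"exact"} computes the true combinatorial maximum
#' from the most even partition of \code{P} patterns into \code{C} symbol
#' groups, \code{(P^2 - sum n_c^2) / (P (P - 1))} per neuron, which equals
#' exhaustive enumeration for all instances; the two methods differ
#' whenever the idealized equal split \code{P/C} is not an integer (the
#' parity cases of the printed form are internally inconsistent, see the
#' package vignette).
#'
#' @param P number of patterns (>= 2).
#' @param C coding level (>= 2).
#' @param M number of readout neurons.
#' @param method \code{"printed"} or \code{"exact"}.
#' @return scalar upper bound for \code{D_inter}.
#' @examples
#' max_inter_distance(15, 2, 8)                    # 4.2857
#' max_inter_distance(15, 2, 8, method = "exact")  # 4.2667
#' @export
max_inter_distance <- function(P, C, M, method = c("printed", "exact")) {
  method <- match.arg(method)
  stopifnot(P >= 2, C >= 2, M >= 1)
  per_neuron <- if (method == "printed") {
    if (P %% 2 == 1) P * (C - 1) / (C * (P - 1)) else (P + 1) * (C - 1) / (C * P)
  } else {
    q <- P %/% C; r <- P %% C
    ssq <- r * (q + 1)^2 + (C - r) * q^2
    (P^2 - ssq) / (P * (P - 1))
  }
  M * per_neuron
}

#' Discriminability index of a probe
#'
#' Combines separability and uniqueness of the readout codes collected
#' during one frozen-plasticity probe.  Separability is
#' \code{epsilon = 1 - D_intra / D_inter}; uniqueness is
#' \code{gamma = (#unique prototypes) / P}; the discriminability index is
#' their product.  \code{D_inter = 0} (all prototypes identical) guards to
#' \code{DI = 0}.  \code{DI} reaches 1 for perfectly repeatable, all-unique
#' codes and may go negative only when \code{D_intra > D_inter}.
#'
#' @param codes_by_pattern list (per pattern) of \code{J x M} symbol
#'   matrices.
#' @return object of class \code{snn_di}: \code{D_intra}, \code{D_inter},
#'   \code{D_inter_max} (printed-form bound at the observed P, C, M),
#'   \code{separability}, \code{uniqueness}, \code{DI}, the prototype
#'   matrix, and the per-pair distance table.
#' @export
discriminability_index <- function(codes_by_pattern) {
  P <- length(codes_by_pattern)
  stopifnot(P >= 2)
  M <- ncol(codes_by_pattern[[1]])
  C_obs <- max(2, max(vapply(codes_by_pattern, max, 0)) + 1)
  protos <- t(vapply(codes_by_pattern, prototype_code, numeric(M)))
  inter <- inter_pattern_distance(protos)
  D_intra <- intra_pattern_distance(codes_by_pattern)
  pairs <- utils::combn(P, 2)
  pair_d <- data.frame(p = pairs[1, ], q = pairs[2, ],
                       distance = vapply(seq_len(ncol(pairs)), function(k)
                         sum(protos[pairs[1, k], ] != protos[pairs[2, k], ]), 0))
  uniq <- length(unique(apply(protos, 1, paste, collapse = ","))) / P
  if (inter$D_inter == 0) {
    eps <- 0; di <- 0
  } else {
    eps <- 1 - D_intra / inter$D_inter
    di <- eps * uniq
  }
  structure(list(D_intra = D_intra, D_inter = inter$D_inter,
                 D_inter_per_neuron = inter$per_neuron,
                 D_inter_max = max_inter_distance(P, C_obs, M),
                 separability = eps, uniqueness = uniq, DI = di,
                 prototypes = protos, pair_distances = pair_d),
            class = "snn_di")
}

#' @export
print.snn_di <- function(x, ...) {
  cat(sprintf("<snn_di> DI = %.3f (separability %.3f x uniqueness %.3f)\n",
              x$DI, x$separability, x$uniqueness))
  cat(sprintf("  D_intra = %.3f, D_inter = %.3f (max %.3f), P = %d\n",
              x$D_intra, x$D_inter, x$D_inter_max, nrow(x$prototypes)))
  invisible(x)
}

#' Serialize a discriminability report as JSON
#'
#' @param report an \code{snn_di} object.
#' @param path file path.
#' @export
write_di_report <- function(report, path) {
  stopifnot(inherits(report, "snn_di"))
  out <- unclass(report)
  out$prototypes <- unname(apply(report$prototypes, 1, paste, collapse = ""))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write readout codes as CSV
#'
#' Columns \code{pattern_id, repeat} then one column of counts or symbols
#' per readout neuron.
#'
#' @param codes_by_pattern list (per pattern) of \code{J x M} matrices.
#' @param path file path.
#' @export
write_codes <- function(codes_by_pattern, path) {
  rows <- do.call(rbind, lapply(seq_along(codes_by_pattern), function(p) {
    m <- codes_by_pattern[[p]]
    cbind(pattern_id = p, rep = seq_len(nrow(m)), as.data.frame(m))
  }))
  names(rows)[-(1:2)] <- paste0("n", seq_len(ncol(rows) - 2))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Fano-factor curve over test durations
#'
#' For each candidate duration \code{d}, presents every pattern
#' \code{trials} times for \code{d} seconds with plasticity frozen and
#' computes the Fano factor of the readout spike counts, averaged across
#' patterns.  By default the factor is computed per readout neuron over its
#' trials and averaged (\code{per_neuron = TRUE}), which isolates
#' trial-to-trial variability; \code{per_neuron = FALSE} pools the
#' \code{M x trials} counts per pattern before taking variance over mean,
#' which additionally picks up the systematic rate differences between
#' readout neurons that carry the code.  A value below 1 marks sub-Poisson
#' regularity of the trained readout; the minimizing \code{d} is the
#' preferred test duration.
#'
#' @param net a trained \code{snn_network}.
#' @param patterns list of patterns.
#' @param d_grid durations to evaluate, in seconds.
#' @param trials repeats per pattern and duration.
#' @param cfg configuration (defaults to the network's).
#' @param per_neuron average per-neuron Fano factors (default) instead of
#'   pooling counts across neurons.
#' @return data frame \code{d, FF} with the argmin attached as attribute
#'   \code{"d_opt"}; cells whose pooled mean count is zero are dropped with
#'   a warning.
#' @export
fano_factor_curve <- function(net, patterns, d_grid, trials = 100, cfg = net$cfg,
                              per_neuron = TRUE) {
  stopifnot(inherits(net, "snn_network"), all(d_grid > 0), trials >= 2)
  ff <- vapply(d_grid, function(d) {
    sched <- test_schedule(patterns, d, trials, cfg, order = "fixed")
    run <- run_network(net, sched, patterns, plasticity = "none", diag_every = 0)
    per_pattern <- vapply(seq_along(patterns), function(p) {
      cnt <- run$sink_counts[, sched$pattern_id == p, drop = FALSE]
      if (per_neuron) {
        v <- apply(cnt, 1, function(x)
          if (mean(x) > 0) stats::var(x) / mean(x) else NA_real_)
        if (all(is.na(v))) return(NA_real_)
        return(mean(v, na.rm = TRUE))
      }
      counts <- as.vector(cnt)
      m <- mean(counts)
      if (m == 0) return(NA_real_)
      stats::var(counts) / m
    }, 0)
    if (anyNA(per_pattern))
      warning("zero-mean spike counts at d = ", d, " for some pattern(s); excluded")
    mean(per_pattern, na.rm = TRUE)
  }, 0)
  out <- data.frame(d = d_grid, FF = ff)
  attr(out, "d_opt") <- d_grid[which.min(ff)]
  out
}
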