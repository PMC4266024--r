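#' Construct the three-layer network
#'
#' Realizes the architecture: K source neurons project to the excitatory
#' reservoir population (E->E, probability \code{c12_ee}); the reservoir
#' holds recurrently connected E and I populations (E->E, E->I, I->E, I->I);
#' reservoir E neurons project to the sink E (readout) neurons, which are
#' reciprocally connected to a small sink I population at full density.
#' Connectivity is independent Bernoulli per potential synapse;
#' within-population recurrent projections exclude self-loops.  Excitatory
#' weights start uniform on (0, \code{w_init_max_ff}) feed-forward/within
#' the reservoir and (0, \code{w_init_max_ro}) onto the readout; inhibitory
#' weights start uniform on (0, \code{z_init_max}).
#'
#' @param cfg an \code{\link{snn_config}}.
#' @param seed optional RNG seed; the same seed reproduces the network.
#' @return an object of class \code{snn_network}: configuration, one
#'   \code{\link{synapse_matrix}} per projection, dynamical state, and the
#'   current simulation time.
#' @examples
#' net <- build_network(snn_config(), seed = 1)
#' net
#' @export
build_network <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "snn_config"))
  if (cfg$K < 1 || cfg$N_E < 1 || cfg$N_I < 1 || cfg$M < 1 || cfg$M_I < 1)
    stop("zero-size layer")
  with_seed(seed, {
    bern <- function(npre, npost, p, self = FALSE) {
      m <- matrix(stats::runif(npre * npost) < p, npre, npost)
      if (self) diag(m) <- FALSE
      m
    }
    init <- function(mask, wmax) matrix(stats::runif(length(mask), 0, wmax),
                                        nrow(mask), ncol(mask)) * mask
    mk <- function(npre, npost, p, wmax, tag, gmax, self = FALSE) {
      m <- bern(npre, npost, p, self)
      synapse_matrix(m, init(m, wmax), tag, gmax)
    }
    proj <- list(
      w12   = mk(cfg$K, cfg$N_E, cfg$c12_ee, cfg$w_init_max_ff, "E->E", cfg$gE_max),
      w22ee = mk(cfg$N_E, cfg$N_E, cfg$c22_ee, cfg$w_init_max_ff, "E->E", cfg$gE_max, self = TRUE),
      w22ei = mk(cfg$N_E, cfg$N_I, cfg$c22_ei, cfg$w_init_max_ff, "E->I", cfg$gE_max),
      w22ie = mk(cfg$N_I, cfg$N_E, cfg$c22_ie, cfg$z_init_max, "I->E", cfg$gI_max),
      w22ii = mk(cfg$N_I, cfg$N_I, cfg$c22_ii, cfg$z_init_max, "I->I", cfg$gI_max, self = TRUE),
      w23   = mk(cfg$N_E, cfg$M, cfg$c23_ee, cfg$w_init_max_ro, "E->E", cfg$gE_max),
      w33ei = mk(cfg$M, cfg$M_I, cfg$c33_ei, cfg$w_init_max_ro, "E->I", cfg$gE_max),
      w33ie = mk(cfg$M_I, cfg$M, cfg$c33_ie, cfg$z_init_max, "I->E", cfg$gI_max)
    )
    n_pop <- c(cfg$K, cfg$N_E, cfg$N_I, cfg$M, cfg$M_I)
    delays <- lapply(n_pop, function(n)
      sample.int(max(1, round(cfg$delay_max / cfg$dt)), n, replace = TRUE))
    structure(list(cfg = cfg, proj = proj, state = init_engine_state(cfg),
                   delays = delays, t = 0),
              class = "snn_network")
  })
}

# flat state list consumed by the C++ engine
init_engine_state <- function(cfg) {
  n <- c(cfg$K, cfg$N_E, cfg$N_I, cfg$M, cfg$M_I)
  st <- list()
  for (pp in 1:4) {
    st[[paste0("V", pp)]] <- rep(cfg$V_rest, n[pp + 1])
    st[[paste0("gex", pp)]] <- numeric(n[pp + 1])
    st[[paste0("ginh", pp)]] <- numeric(n[pp + 1])
  }
  for (pp in 0:4) st[[paste0("last", pp)]] <- rep(-1e9, n[pp + 1])
  st$t <- 0
  st
}

layer_names <- c("source", "reservoir_E", "reservoir_I", "sink_E", "sink_I")

# per-projection all-to-all flags for the E-STDP pairing scheme, in the
# engine's projection order (inhibitory entries are ignored by the engine)
pairing_flags <- function(cfg) {
  nm <- c("w12", "w22ee", "w22ei", "w22ie", "w22ii", "w23", "w33ei", "w33ie")
  p <- cfg$estdp_pairing
  if (length(p) == 1 && is.null(names(p))) p <- setNames(rep(p, 8), nm)
  else {
    full <- setNames(rep("all", 8), nm)
    full[names(p)] <- p
    p <- full
  }
  as.integer(p[nm] == "all")
}

#' Run the simulation loop over a stimulus schedule
#'
#' Advances the full network one millisecond step at a time: scheduled
#' Poisson source spikes are generated, the previous step's spikes are
#' delivered to the conductances (one-step synaptic delay), membranes take
#' one Euler step with threshold/reset, and - unless plasticity is frozen -
#' both STDP rules update all synapse classes.  All randomness draws from
#' R's RNG, so a prior \code{set.seed()} makes runs bit-reproducible.
#'
#' @param net an \code{\link{build_network}} object.
#' @param schedule a schedule data frame (\code{pattern_id, duration_ms});
#'   \code{pattern_id = 0} presents a blank stimulus.
#' @param patterns list of \code{\link{snn_pattern}} objects indexed by
#'   \code{pattern_id}.
#' @param plasticity \code{TRUE} (both rules), \code{FALSE} (frozen), or a
#'   character flag: \code{"both"}, \code{"none"}, \code{"no_istdp"}
#'   (E-STDP only with fixed inhibitory weights - the balance ablation), or
#'   \code{"no_estdp"}.
#' @param diag_every interval in steps between diagnostics rows (mean
#'   excitatory/inhibitory/net current and firing rate over the reservoir E
#'   population); 0 disables.
#' @param record \code{"none"}, \code{"network"} (reservoir + sink spikes)
#'   or \code{"all"} (including source spikes).
#' @return a list of class \code{snn_run}: the updated network, per-segment
#'   sink spike counts (\code{M x n_segments}), per-segment reservoir spike
#'   counts, a diagnostics data frame, and (optionally) the spike record
#'   with columns \code{layer, neuron_id, time_ms}.
#' @export
run_network <- function(net, schedule, patterns, plasticity = TRUE,
                        diag_every = 1000, record = c("none", "network", "all")) {
  stopifnot(inherits(net, "snn_network"))
  record <- match.arg(record)
  if (is.logical(plasticity)) plasticity <- if (plasticity) "both" else "none"
  plasticity <- match.arg(plasticity, c("both", "none", "no_istdp", "no_estdp"))
  cfg <- net$cfg
  if (nrow(schedule) == 0) {
    return(structure(list(net = net, sink_counts = matrix(0L, cfg$M, 0),
                          resE_counts = integer(0), resI_counts = integer(0),
                          seg_ms = integer(0),
                          diag = empty_diag(), spikes = empty_spikes()),
                     class = "snn_run"))
  }
  pm <- pattern_matrix(patterns, cfg)
  if (any(schedule$pattern_id > ncol(pm)))
    stop("schedule references a pattern beyond the supplied list")
  steps <- as.integer(round(schedule$duration_ms / cfg$dt))
  if (any(steps < 1)) stop("schedule segment shorter than one time step")
  par <- list(dt = cfg$dt, tau_m = cfg$tau_m, V_T = cfg$V_T, V_rest = cfg$V_rest,
              V_reset = cfg$V_reset, E_ex = cfg$E_ex, E_inh = cfg$E_inh,
              tau_AMPA = cfg$tau_AMPA, tau_GABA = cfg$tau_GABA,
              g_leak = cfg$g_leak, g_leak_gaba = cfg$g_leak_gaba,
              ref_steps = as.integer(round(cfg$t_ref / cfg$dt)),
              ref_steps_inh = as.integer(round(cfg$t_ref_inh / cfg$dt)),
              A_plus = cfg$A_plus, A_minus = cfg$A_minus,
              A_minus_readout = cfg$A_minus_readout,
              tau_plus = cfg$tau_plus, tau_minus = cfg$tau_minus,
              B_plus = cfg$B_plus, B_minus = cfg$B_minus, tau_i = cfg$tau_i,
              gE_max = cfg$gE_max, gI_max = cfg$gI_max,
              p_black = cfg$f_black * cfg$dt / 1000,
              p_noise = cfg$f_noise * cfg$dt / 1000,
              noise_fraction = cfg$noise_fraction, exact_decay = cfg$exact_decay,
              bg_p = cfg$f_bg * cfg$dt / 1000, bg_w = cfg$w_bg,
              estdp_all_to_all = pairing_flags(cfg))
  Wl <- lapply(net$proj, `[[`, "weights")
  Ml <- lapply(net$proj, function(p) matrix(as.integer(p$mask), nrow(p$mask)))
  out <- engine_run(Wl, Ml, net$state, net$delays, pm,
                    as.integer(schedule$pattern_id), steps, par,
                    estdp_on = plasticity %in% c("both", "no_istdp"),
                    istdp_on = plasticity %in% c("both", "no_estdp"),
                    diag_every = as.integer(diag_every),
                    record = match(record, c("none", "network", "all")) - 1L)
  for (nm in names(net$proj)) net$proj[[nm]]$weights <- out$W[[nm]]
  net$state <- out$state
  net$t <- out$state$t
  spikes <- data.frame(layer = layer_names[out$spikes$layer + 1L],
                       neuron_id = out$spikes$neuron_id,
                       time_ms = out$spikes$time_ms)
  structure(list(net = net, sink_counts = out$sink_counts,
                 resE_counts = out$resE_counts, resI_counts = out$resI_counts,
                 seg_ms = out$seg_ms,
                 diag = as.data.frame(out$diag), spikes = spikes),
            class = "snn_run")
}

empty_diag <- function() data.frame(time_ms = numeric(0), mean_Iex = numeric(0),
                                    mean_Iinh = numeric(0), mean_Inet = numeric(0),
                                    mean_rate_hz = numeric(0))
empty_spikes <- function() data.frame(layer = character(0), neuron_id = integer(0),
                                      time_ms = numeric(0))

#' Mean reservoir firing rate of a run
#'
#' Population-mean rate (Hz) of the reservoir E neurons over the whole run.
#'
#' @param run an \code{snn_run} object.
#' @return scalar rate in Hz.
#' @export
reservoir_rate <- function(run) {
  stopifnot(inherits(run, "snn_run"))
  tot_ms <- sum(run$seg_ms)
  if (tot_ms == 0) return(NA_real_)
  sum(run$resE_counts) / run$net$cfg$N_E / (tot_ms / 1000)
}

#' Frozen-plasticity discriminability probe
#'
#' Presents every pattern \code{J} times for \code{d_s} seconds with
#' plasticity turned off, extracts one rate code per presentation from the
#' sink spike counts, and computes the full discriminability report.  The
#' probe is side-effect free: the training state of \code{net} is left
#' untouched (the caller's object is not modified).
#'
#' @param net an \code{snn_network}.
#' @param patterns list of patterns to probe.
#' @param cfg configuration (defaults to the network's).
#' @param d_s,J,C probe parameters (default from \code{cfg}).
#' @param order presentation order, see \code{\link{test_schedule}}.
#' @return a \code{\link{discriminability_index}} report with the per-code
#'   spike counts attached as attribute \code{"counts"}.
#' @export
probe_di <- function(net, patterns, cfg = net$cfg, d_s = cfg$d_test, J = cfg$J,
                     C = cfg$C, order = "fixed") {
  sched <- test_schedule(patterns, d_s, J, cfg, order = order)
  run <- run_network(net, sched, patterns, plasticity = "none", diag_every = 0)
  codes_by_pattern <- split_codes(run$sink_counts, sched$pattern_id, C)
  rep <- discriminability_index(codes_by_pattern)
  attr(rep, "counts") <- run$sink_counts
  attr(rep, "pattern_id") <- sched$pattern_id
  rep
}

# sink count matrix (M x nseg) -> list (per pattern) of J x M symbol matrices
split_codes <- function(counts, pattern_id, C) {
  lapply(sort(unique(pattern_id)), function(p) {
    segs <- which(pattern_id == p)
    t(vapply(segs, function(s) rate_code(counts[, s], C), numeric(nrow(counts))))
  })
}

#' Shuffle learned connectivity while preserving weights
#'
#' Control experiments on a trained network: the presynaptic assignment of
#' every realized synapse is permuted within the allowed source population
#' (per postsynaptic neuron, preserving in-degree, weight multiset and
#' synapse count), destroying the learned wiring but not the weight
#' statistics.  Cases: 1 = source->reservoir E synapses; 2 = all
#' intra-reservoir projections; 3 = reservoir I->{E,I} only; 4 = reservoir
#' E->{E,I} only; 5 = reservoir->readout E->E; 6 = all of 1-5.
#'
#' @param net a trained \code{snn_network}.
#' @param case integer 1..6.
#' @param seed optional RNG seed.
#' @return the shuffled \code{snn_network}.
#' @export
shuffle_connectivity <- function(net, case, seed = NULL) {
  stopifnot(inherits(net, "snn_network"))
  if (!case %in% 1:6) stop("unknown shuffle case: ", case)
  which_proj <- switch(case,
    `1` = "w12",
    `2` = c("w22ee", "w22ei", "w22ie", "w22ii"),
    `3` = c("w22ie", "w22ii"),
    `4` = c("w22ee", "w22ei"),
    `5` = "w23",
    `6` = c("w12", "w22ee", "w22ei", "w22ie", "w22ii", "w23"))
  with_seed(seed, {
    for (nm in which_proj) {
      syn <- net$proj[[nm]]
      self_excluded <- nm %in% c("w22ee", "w22ii")
      npre <- nrow(syn$mask)
      newmask <- matrix(FALSE, npre, ncol(syn$mask))
      newW <- matrix(0, npre, ncol(syn$mask))
      for (j in seq_len(ncol(syn$mask))) {
        old_pre <- which(syn$mask[, j])
        deg <- length(old_pre)
        if (deg == 0) next
        pool <- if (self_excluded) setdiff(seq_len(npre), j) else seq_len(npre)
        new_pre <- sample(pool, deg)
        newmask[new_pre, j] <- TRUE
        newW[new_pre, j] <- syn$weights[old_pre, j]
      }
      syn$mask <- newmask
      syn$weights <- newW
      net$proj[[nm]] <- syn
    }
    net
  })
}

#' Save or load a network checkpoint
#'
#' Serializes the full network (configuration, weights, masks, dynamic
#' state, simulation clock) to a single file.
#'
#' @param net an \code{snn_network}.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "snn_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "snn_network"))
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network>\n")
  cat(sprintf("  layers: %d source -> %d E + %d I reservoir -> %d E + %d I sink\n",
              x$cfg$K, x$cfg$N_E, x$cfg$N_I, x$cfg$M, x$cfg$M_I))
  n_syn <- sum(vapply(x$proj, function(p) sum(p$mask), 0))
  cat(sprintf("  %d synapses across %d projections; t = %.1f s\n",
              n_syn, length(x$proj), x$t / 1000))
  invisible(x)
}

#' @export
summary.snn_network <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$proj), function(nm) {
    p <- object$proj[[nm]]
    w <- p$weights[p$mask]
    data.frame(projection = nm, class = p$class_tag, n_synapses = sum(p$mask),
               density = mean(p$mask), mean_w = mean(w),
               frac_strong = mean(w > 0.7 * p$g_max))
  }))
  cat(sprintf("Network at t = %.1f s\n", object$t / 1000))
  print(tab, row.names = FALSE, digits = 3)
  invisible(tab)
}
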