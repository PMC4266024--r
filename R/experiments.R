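#' Train a network with periodic frozen discriminability probes
#'
#' The main fitting routine: alternates plastic training segments (random
#' pattern order, exponential presentation durations) with frozen-plasticity
#' probes in which every pattern is presented \code{J} times for
#' \code{d_test} seconds and the discriminability index is computed.
#' Training resumes from the pre-probe state, so probes are side-effect
#' free and probe time does not count toward training time.
#'
#' @param net an \code{\link{build_network}} object (or \code{NULL} to build
#'   one from \code{cfg}).
#' @param patterns list of \code{\link{snn_pattern}} objects.
#' @param total_s total training time in simulated seconds.
#' @param probe_every_s interval between probes (seconds); \code{Inf}
#'   disables probing.
#' @param plasticity plasticity mode for the training segments, see
#'   \code{\link{run_network}}; the balance ablation uses
#'   \code{"no_istdp"}.
#' @param cfg configuration, defaults to the network's.
#' @param probe_patterns patterns probed for DI (defaults to
#'   \code{patterns}; the stability protocols probe the union of old and
#'   new sets).
#' @param probe_at_start probe the untrained network before training
#'   begins.
#' @param snapshots keep a binarized snapshot of the source->reservoir
#'   weights at every probe (for synaptic-distance tracking).
#' @param seed optional RNG seed for the whole run.
#' @return an object of class \code{snn_fit}: the trained network, a
#'   \code{di_series} data frame (\code{time_s, DI, separability,
#'   uniqueness, D_intra, D_inter}), the concatenated training diagnostics
#'   (currents and rates), probe reports, and optional snapshots.
#' @examples
#' \donttest{
#' cfg <- snn_config("desk")
#' pats <- flag_patterns(4, cfg$image_size, seed = 2)
#' fit <- train_network(build_network(cfg, seed = 1), pats,
#'                      total_s = 20, probe_every_s = 10, seed = 3)
#' fit
#' }
#' @export
train_network <- function(net = NULL, patterns, total_s, probe_every_s = 10,
                          plasticity = "both", cfg = NULL,
                          probe_patterns = patterns, probe_at_start = FALSE,
                          snapshots = FALSE, seed = NULL) {
  if (is.null(net)) net <- build_network(if (is.null(cfg)) snn_config() else cfg)
  cfg <- net$cfg
  stopifnot(total_s > 0)
  with_seed(seed, {
    t_start <- net$t / 1000
    di_rows <- list(); reports <- list(); snaps <- list(); diag <- list()
    do_probe <- function(t_now) {
      rep <- probe_di(net, probe_patterns, cfg)
      di_rows[[length(di_rows) + 1]] <<- data.frame(
        time_s = t_now, DI = rep$DI, separability = rep$separability,
        uniqueness = rep$uniqueness, D_intra = rep$D_intra,
        D_inter = rep$D_inter)
      reports[[length(reports) + 1]] <<- rep
      if (snapshots)
        snaps[[length(snaps) + 1]] <<- list(time_s = t_now,
                                            W12 = binarize_weights(net$proj$w12))
    }
    if (probe_at_start && is.finite(probe_every_s)) do_probe(t_start)
    elapsed <- 0
    while (elapsed < total_s) {
      chunk <- min(probe_every_s, total_s - elapsed)
      sched <- training_schedule(patterns, chunk * 1000, cfg)
      run <- run_network(net, sched, patterns, plasticity = plasticity,
                         diag_every = 1000)
      net <- run$net
      diag[[length(diag) + 1]] <- run$diag
      elapsed <- elapsed + chunk
      if (is.finite(probe_every_s)) do_probe(t_start + elapsed)
    }
    structure(list(net = net, cfg = cfg, patterns = patterns,
                   plasticity = plasticity, total_s = total_s,
                   di_series = if (length(di_rows)) do.call(rbind, di_rows)
                               else empty_di_series(),
                   diagnostics = do.call(rbind, diag),
                   reports = reports, snapshots = snaps),
              class = "snn_fit")
  })
}

empty_di_series <- function() data.frame(time_s = numeric(0), DI = numeric(0),
                                         separability = numeric(0),
                                         uniqueness = numeric(0),
                                         D_intra = numeric(0), D_inter = numeric(0))

#' @export
print.snn_fit <- function(x, ...) {
  cat("<snn_fit>\n")
  cat(sprintf("  trained %g s (%s plasticity) on %d patterns; t = %.1f s\n",
              x$total_s, x$plasticity, length(x$patterns), x$net$t / 1000))
  if (nrow(x$di_series)) {
    n <- nrow(x$di_series)
    cat(sprintf("  DI: final %.3f, mean %.3f over %d probes\n",
                x$di_series$DI[n], mean(x$di_series$DI), n))
  }
  if (!is.null(x$diagnostics) && nrow(x$diagnostics))
    cat(sprintf("  reservoir rate %.1f Hz; |I_net|/I_ex = %.3f (final windows)\n",
                mean(utils::tail(x$diagnostics$mean_rate_hz, 10)),
                mean(abs(utils::tail(x$diagnostics$mean_Inet, 10))) /
                  mean(utils::tail(x$diagnostics$mean_Iex, 10))))
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, ...) {
  print(object)
  cat("\nProjection summary:\n")
  summary(object$net)
}

#' @export
coef.snn_fit <- function(object, ...) {
  lapply(object$net$proj, `[[`, "weights")
}

#' @export
plot.snn_fit <- function(x, which = c("di", "weights", "balance"), ...) {
  which <- match.arg(which)
  if (which == "di" && nrow(x$di_series)) {
    graphics::plot(x$di_series$time_s, x$di_series$DI, type = "b",
                   xlab = "training time (s)", ylab = "DI", ylim = c(0, 1), ...)
  } else if (which == "weights") {
    w <- x$net$proj$w12
    graphics::hist(w$weights[w$mask] / w$g_max, breaks = 30,
                   xlab = "w / gE_max", main = "source->reservoir weights", ...)
  } else if (which == "balance" && nrow(x$diagnostics)) {
    d <- x$diagnostics
    graphics::matplot(d$time_ms / 1000, cbind(d$mean_Iex, d$mean_Iinh, d$mean_Inet),
                      type = "l", lty = 1, col = c("darkgreen", "red", "blue"),
                      xlab = "time (s)", ylab = "mean current", ...)
    graphics::legend("topright", c("I_ex", "I_inh", "I_net"), lty = 1,
                     col = c("darkgreen", "red", "blue"), bty = "n")
  }
  invisible(x)
}

#' @export
predict.snn_fit <- function(object, patterns = object$patterns, ...) {
  probe_di(object$net, patterns, object$cfg)
}

#' @export
simulate.snn_fit <- function(object, nsim = 1, seed = NULL, patterns = object$patterns,
                             d_s = object$cfg$d_test, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      sched <- test_schedule(patterns, d_s, 1, object$cfg)
      run <- run_network(object$net, sched, patterns, plasticity = "none",
                         diag_every = 0)
      run$sink_counts
    })
  })
}

#' Matched balance ablation: I-STDP on vs off
#'
#' Trains two networks from the same initial wiring and seed, one with both
#' STDP rules active and one with inhibitory plasticity disabled
#' (inhibitory weights fixed at their random initialization), and reports
#' the paired diagnostics: mean reservoir rates, current balance
#' (time-averaged |I_net| / I_ex), strong-synapse statistics of the
#' receptive fields, and the DI time series of both conditions.
#'
#' @param cfg an \code{\link{snn_config}}.
#' @param patterns training patterns.
#' @param total_s training length in seconds.
#' @param probe_every_s DI probe cadence (seconds).
#' @param seed RNG seed shared by the two conditions.
#' @return list of class \code{snn_ablation} with elements \code{on},
#'   \code{off} (both \code{snn_fit}) and a \code{comparison} data frame.
#' @export
istdp_ablation <- function(cfg, patterns, total_s, probe_every_s = 10, seed = 1) {
  net0 <- build_network(cfg, seed = seed)
  fit_on <- train_network(net0, patterns, total_s, probe_every_s,
                          plasticity = "both", seed = seed + 1)
  fit_off <- train_network(net0, patterns, total_s, probe_every_s,
                           plasticity = "no_istdp", seed = seed + 1)
  summ <- function(fit, label) {
    d <- fit$diagnostics
    data.frame(condition = label,
               mean_rate_hz = mean(d$mean_rate_hz),
               balance = mean(abs(d$mean_Inet)) / mean(d$mean_Iex),
               strong_frac_12 = strong_fraction(fit$net, "w12"),
               rf_empty = mean(vapply(seq_len(cfg$N_E), function(i)
                 !any(receptive_field(fit$net, i)$strong), TRUE)),
               mean_DI = if (nrow(fit$di_series)) mean(fit$di_series$DI) else NA_real_)
  }
  structure(list(on = fit_on, off = fit_off,
                 comparison = rbind(summ(fit_on, "istdp_on"),
                                    summ(fit_off, "istdp_off"))),
            class = "snn_ablation")
}

#' @export
print.snn_ablation <- function(x, ...) {
  cat("<snn_ablation> I-STDP on vs off\n")
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Parameter sweeps of the discriminability index
#'
#' Re-trains the network across a grid of one parameter (coding level
#' \code{C}, readout count \code{M}, reservoir recurrence \code{c22_ee} or
#' readout connectivity \code{c23_ee}) and reports mean and sd of the
#' final-probe DI over \code{n_seeds} replicate networks per grid cell.
#'
#' @param cfg base configuration.
#' @param patterns training patterns.
#' @param param one of \code{"C"}, \code{"M"}, \code{"c22_ee"},
#'   \code{"c23_ee"}.
#' @param values grid of values for the swept parameter.
#' @param total_s training length per cell (seconds).
#' @param n_seeds replicate networks per cell.
#' @param seed base RNG seed.
#' @return data frame \code{value, mean_DI, sd_DI, n}.
#' @export
parameter_sweep <- function(cfg, patterns, param = c("C", "M", "c22_ee", "c23_ee"),
                            values, total_s, n_seeds = 3, seed = 1) {
  param <- match.arg(param)
  rows <- lapply(values, function(v) {
    args <- stats::setNames(list(v), param)
    cfg_v <- do.call(snn_config, c(list(preset = "desk"), unclass(cfg)[
      setdiff(names(unclass(cfg)), c(param, "A_minus", "A_minus_readout"))], args))
    di <- vapply(seq_len(n_seeds), function(s) {
      fit <- train_network(build_network(cfg_v, seed = seed + s), patterns,
                           total_s, probe_every_s = total_s, seed = seed + 100 + s)
      utils::tail(fit$di_series$DI, 1)
    }, 0)
    data.frame(value = v, mean_DI = mean(di), sd_DI = stats::sd(di), n = n_seeds)
  })
  do.call(rbind, rows)
}

#' Stability-plasticity protocol
#'
#' Phase 1 trains on the old pattern set; phase 2 continues with the union
#' of old and new patterns (\code{mode = "old+new"}), with the new patterns
#' only (\code{mode = "new-only"}), or with the original set again
#' (\code{mode = "old-only"}, the pure stability control).  Throughout
#' phase 2 the DI is probed on the union of all patterns and the relative
#' synaptic distance of the source->reservoir weights is tracked against
#' the phase-1 endpoint snapshot.
#'
#' @param cfg configuration.
#' @param old_patterns,new_patterns the two pattern sets.
#' @param phase_s length of each phase in seconds.
#' @param mode \code{"old+new"} or \code{"new-only"}.
#' @param probe_every_s DI probe cadence in phase 2.
#' @param phi_every_s synaptic snapshot cadence in phase 2 (seconds).
#' @param n_shuffles shuffles for the chance-level distance.
#' @param seed RNG seed.
#' @param phase1_fit optionally, a pre-trained phase-1 \code{snn_fit} to
#'   continue from (lets several modes share one phase 1).
#' @return list of class \code{snn_stability}: phase-1 fit, phase-2 fit,
#'   \code{di_series} (phase-2 DI on the union), and \code{phi_series}
#'   (\code{time_s, phi, phi_shuffled, phi_rel}).
#' @export
stability_plasticity <- function(cfg, old_patterns, new_patterns, phase_s,
                                 mode = c("old+new", "new-only", "old-only"),
                                 probe_every_s = 60, phi_every_s = 10,
                                 n_shuffles = 10, seed = 1, phase1_fit = NULL) {
  mode <- match.arg(mode)
  if (is.null(phase1_fit)) {
    phase1_fit <- train_network(build_network(cfg, seed = seed), old_patterns,
                                phase_s, probe_every_s = Inf, seed = seed + 1)
  }
  net <- phase1_fit$net
  ref_snap <- binarize_weights(net$proj$w12)
  train_set <- switch(mode, "old+new" = c(old_patterns, new_patterns),
                      "new-only" = new_patterns, "old-only" = old_patterns)
  union_set <- if (mode == "old-only") old_patterns else c(old_patterns, new_patterns)

  with_seed(seed + 2, {
    di_rows <- list(); phi_rows <- list()
    elapsed <- 0
    next_probe <- probe_every_s
    while (elapsed < phase_s) {
      chunk <- min(phi_every_s, phase_s - elapsed)
      sched <- training_schedule(train_set, chunk * 1000, cfg)
      run <- run_network(net, sched, train_set, plasticity = "both",
                         diag_every = 0)
      net <- run$net
      elapsed <- elapsed + chunk
      snap <- binarize_weights(net$proj$w12)
      phi <- synaptic_distance(ref_snap, snap)
      phi_sh <- shuffled_distance(ref_snap, snap, n_shuffles)
      phi_rows[[length(phi_rows) + 1]] <- data.frame(
        time_s = elapsed, phi = phi, phi_shuffled = phi_sh,
        phi_rel = relative_distance(phi, phi_sh))
      if (elapsed >= next_probe - 1e-9) {
        rep <- probe_di(net, union_set, cfg)
        di_rows[[length(di_rows) + 1]] <- data.frame(time_s = elapsed, DI = rep$DI,
                                                     separability = rep$separability,
                                                     uniqueness = rep$uniqueness)
        next_probe <- next_probe + probe_every_s
      }
    }
    structure(list(phase1 = phase1_fit, mode = mode,
                   net = net,
                   di_series = if (length(di_rows)) do.call(rbind, di_rows)
                               else empty_di_series()[, 1:4],
                   phi_series = do.call(rbind, phi_rows)),
              class = "snn_stability")
  })
}

#' @export
print.snn_stability <- function(x, ...) {
  cat(sprintf("<snn_stability> mode %s\n", x$mode))
  if (nrow(x$di_series))
    cat(sprintf("  phase-2 DI on union: mean %.3f, final %.3f\n",
                mean(x$di_series$DI), utils::tail(x$di_series$DI, 1)))
  cat(sprintf("  phi_rel final %.3f\n", utils::tail(x$phi_series$phi_rel, 1)))
  invisible(x)
}

#' Connectivity- and readout-shuffle controls
#'
#' Evaluates a trained network against its shuffled controls: for each
#' connectivity-shuffle case (1..6) the DI is measured over
#' \code{n_shuffles} independent shuffles and averaged, plus a readout-code
#' control in which the recorded code symbols are independently permuted
#' within each code.
#'
#' @param net a trained \code{snn_network}.
#' @param patterns probe patterns.
#' @param cases integer subset of 1..6.
#' @param n_shuffles shuffles per case.
#' @param cfg configuration (defaults to the network's).
#' @param seed RNG seed.
#' @return data frame \code{case, mean_DI, sd_DI} with case
#'   \code{"unshuffled"} and \code{"code-shuffle"} rows included.
#' @export
shuffle_controls <- function(net, patterns, cases = 1:6, n_shuffles = 10,
                             cfg = net$cfg, seed = 1) {
  with_seed(seed, {
    base_rep <- probe_di(net, patterns, cfg)
    rows <- list(data.frame(case = "unshuffled", mean_DI = base_rep$DI,
                            sd_DI = NA_real_))
    for (cs in cases) {
      di <- vapply(seq_len(n_shuffles), function(k) {
        probe_di(shuffle_connectivity(net, cs), patterns, cfg)$DI
      }, 0)
      rows[[length(rows) + 1]] <- data.frame(case = paste0("case", cs),
                                             mean_DI = mean(di), sd_DI = stats::sd(di))
    }
    # readout-code control: permute symbols independently within each code
    counts <- attr(base_rep, "counts")
    pid <- attr(base_rep, "pattern_id")
    di_code <- vapply(seq_len(n_shuffles), function(k) {
      codes <- split_codes(counts, pid, cfg$C)
      codes <- lapply(codes, function(m) t(apply(m, 1, sample)))
      discriminability_index(codes)$DI
    }, 0)
    rows[[length(rows) + 1]] <- data.frame(case = "code-shuffle",
                                           mean_DI = mean(di_code),
                                           sd_DI = stats::sd(di_code))
    do.call(rbind, rows)
  })
}
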