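# shared helpers: miniature configurations, pattern sets, and a pure-R
# reference implementation of the simulation loop built from the exported
# per-step operations (used as the independent oracle for the C++ engine)

tiny_cfg <- function(...) {
  snn_config("desk", image_size = 5, K = 25, N_E = 6, N_I = 3, M = 2, M_I = 2,
             J = 2, ...)
}

desk_patterns <- function(n = 8, cfg = snn_config("desk"), seed = 11) {
  flag_patterns(n, cfg$image_size, seed = seed)
}

# reference simulation: nearest-neighbour pairing, unit delays, no
# refractory, no background -- the configuration in which the exported R
# operations compose to exactly the engine's update
reference_cfg <- function(...) {
  tiny_cfg(delay_max = 1, t_ref = 0, t_ref_inh = 0, f_bg = 0,
           noise_fraction = 0, estdp_pairing = "nearest",
           g_leak = 0.5, g_leak_gaba = 0.5, ...)
}

reference_run <- function(net, steps, p_spike) {
  cfg <- net$cfg
  n <- c(cfg$K, cfg$N_E, cfg$N_I, cfg$M, cfg$M_I)
  pops <- lapply(n[2:5], neuron_state, cfg = cfg)
  last <- lapply(n, function(k) rep(-Inf, k))
  prev <- lapply(n, function(k) logical(k))
  # projection table in engine order: name, pre pop, post pop, excitatory,
  # feed-forward balance (E->I and readout classes)
  tab <- list(
    list("w12", 1, 2, TRUE, FALSE),  list("w22ee", 2, 2, TRUE, FALSE),
    list("w22ei", 2, 3, TRUE, TRUE), list("w22ie", 3, 2, FALSE, FALSE),
    list("w22ii", 3, 3, FALSE, FALSE), list("w23", 2, 4, TRUE, TRUE),
    list("w33ei", 4, 5, TRUE, TRUE), list("w33ie", 5, 4, FALSE, FALSE))
  for (t in seq_len(steps)) {
    src <- stats::runif(cfg$K) < p_spike
    inc_ex <- lapply(n[2:5], numeric)
    inc_in <- lapply(n[2:5], numeric)
    for (pr in tab) {
      sp <- prev[[pr[[2]]]]
      if (!any(sp)) next
      W <- net$proj[[pr[[1]]]]$weights
      add <- colSums(W[sp, , drop = FALSE])
      k <- pr[[3]] - 1
      if (pr[[4]]) inc_ex[[k]] <- inc_ex[[k]] + add
      else inc_in[[k]] <- inc_in[[k]] + add
    }
    cur <- vector("list", 5)
    cur[[1]] <- src
    for (k in 1:4) {
      pops[[k]] <- step_conductances(pops[[k]], inc_ex[[k]], inc_in[[k]], cfg)
      pops[[k]] <- step_membrane(pops[[k]], cfg, t_now = t)
      cur[[k + 1]] <- pops[[k]]$spiked_now
    }
    for (pr in tab) {
      amp <- if (pr[[5]]) cfg$A_minus_readout else cfg$A_minus
      net$proj[[pr[[1]]]] <- apply_stdp(
        net$proj[[pr[[1]]]], cur[[pr[[2]]]], cur[[pr[[3]]]],
        last[[pr[[2]]]], last[[pr[[3]]]], t, cfg, depression_amp = amp)
    }
    for (k in 1:5) last[[k]][cur[[k]]] <- t
    prev <- cur
  }
  list(net = net, V = lapply(pops, `[[`, "V"),
       g_ex = lapply(pops, `[[`, "g_ex"), g_inh = lapply(pops, `[[`, "g_inh"))
}
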