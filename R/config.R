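#' Network and protocol configuration
#'
#' Builds the complete parameter set for the three-layer spiking network:
#' leaky integrate-and-fire membrane constants, AMPA/GABA conductance
#' kinetics, the excitatory (anti-symmetric) and inhibitory (symmetric) STDP
#' rules, layer sizes, connection probabilities, the Poisson image encoder,
#' and the testing protocol (presentation duration \code{d_test}, repeats
#' \code{J}, coding level \code{C}).
#'
#' Two presets are provided.  \code{"paper"} is the full-size configuration
#' (30 x 30 images, K = 900 source neurons, 200 excitatory + 50 inhibitory
#' reservoir neurons, J = 10).  \code{"desk"} is a proportionally scaled
#' configuration (15 x 15 images, K = 225, 100 + 25 reservoir neurons,
#' J = 5) suitable for interactive work and continuous testing; it keeps
#' every membrane, synaptic and plasticity constant identical to the
#' full-size model and scales only the population sizes and probe repeats.
#'
#' Conductances and synaptic weights are treated as dimensionless multipliers
#' of the driving force (the membrane equation divides by no capacitance);
#' the "nS" labels on \code{A_plus}, \code{gE_max} etc. are naming
#' conventions inherited from the biophysical reading of the model.
#'
#' The depression amplitude \code{A_minus} is not a free parameter: it is
#' derived from the depression/potentiation balance
#' \code{beta = A_minus * tau_minus / (A_plus * tau_plus)}, so
#' \code{A_minus = beta * A_plus * tau_plus / tau_minus} (0.00525 at the
#' defaults, a slight bias toward depression for \code{beta} = 1.05).
#'
#' @param preset \code{"desk"} (default) or \code{"paper"}.
#' @param ... named overrides for any configuration field (see Details).
#'
#' @details Fields and defaults (desk preset in parentheses where different):
#' \describe{
#'   \item{membrane}{\code{tau_m} 20 ms, \code{V_T} -54 mV, \code{V_rest}
#'     -74 mV, \code{V_reset} -60 mV, \code{E_ex} 0 mV, \code{E_inh} -80 mV,
#'     \code{dt} 1 ms; absolute refractory periods \code{t_ref} 5 ms
#'     (excitatory) and \code{t_ref_inh} 4 ms (inhibitory, fast-spiking).}
#'   \item{conductances}{\code{tau_AMPA} 40 ms, \code{tau_GABA} 50 ms;
#'     \code{exact_decay = FALSE} uses the same explicit Euler
#'     discretization as the membrane (\code{g <- g * (1 - dt/tau)}),
#'     \code{TRUE} switches to exact exponential decay.  Conductances enter
#'     the membrane equation in units of the leak conductance: one AMPA
#'     weight unit counts as \code{1/g_leak} (default 8) leak units, one
#'     GABA unit as \code{1/g_leak_gaba} (default 3.2) - the unit
#'     reconciliation of the nominally-nS synaptic scale with the unitless
#'     membrane equation (see the package vignette).}
#'   \item{E-STDP}{\code{A_plus} 0.005, \code{beta} 1.05, \code{tau_plus}
#'     20 ms, \code{tau_minus} 20 ms, \code{gE_max} 0.3.
#'     \code{beta_readout} 0.8 is the depression/potentiation balance of
#'     the purely feed-forward classes (E->I and reservoir->readout), whose
#'     reported end state is uniform saturation.  \code{estdp_pairing}
#'     selects the spike-pairing scheme per projection: trace-based
#'     \code{"all"}-to-all on feed-forward projections, \code{"nearest"}
#'     neighbour on recurrent E->E (a single string applies to every
#'     projection).}
#'   \item{I-STDP}{\code{B_plus} 0.0015, \code{B_minus} 0.0003,
#'     \code{tau_i} 10 ms, \code{gI_max} 0.2 (always nearest-neighbour
#'     pairing).}
#'   \item{architecture}{\code{image_size} 30 (15), \code{K} 900 (225),
#'     \code{N_E} 200 (100), \code{N_I} 50 (25), \code{M} 8, \code{M_I} 6;
#'     connection probabilities \code{c12_ee} 0.2, \code{c22_ee} 0.4,
#'     \code{c22_ei} 0.4, \code{c22_ie} 0.5, \code{c22_ii} 0.5,
#'     \code{c23_ee} 0.3, \code{c33_ei} 1, \code{c33_ie} 1; per-neuron
#'     axonal conduction delays uniform on 1..\code{delay_max} (10) ms.}
#'   \item{background}{independent Poisson afferents at \code{f_bg} 500 Hz
#'     with weight \code{w_bg} 0.1 onto every reservoir and sink neuron,
#'     keeping the network fluctuation-driven (spontaneous activity).}
#'   \item{initial weights}{\code{w_init_max_ff} 0.1 (feed-forward 1->2 and
#'     all within-reservoir E synapses), \code{w_init_max_ro} 0.2
#'     (reservoir->readout), \code{z_init_max} 0.1 (all inhibitory
#'     synapses).}
#'   \item{encoder}{\code{f_black} 90 Hz, \code{f_noise} 10 Hz,
#'     \code{noise_fraction} 0.1 (fraction of white-pixel neurons emitting
#'     noise spikes, redrawn every presentation).}
#'   \item{protocol}{\code{mean_pattern_duration} 30 ms,
#'     \code{d_test} 1.4 s, \code{J} 10 (5), \code{C} 3.}
#' }
#'
#' The sink inhibitory pool size \code{M_I} regulates readout competition;
#' 6 neurons hold the readout in its pattern-sensitive range.
#'
#' @return An object of class \code{snn_config} (a validated named list).
#' @examples
#' cfg <- snn_config()
#' cfg$A_minus            # derived from beta
#' cfg2 <- snn_config("paper", c22_ee = 0.6)
#' @export
snn_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    # membrane
    tau_m = 20, V_T = -54, V_rest = -74, V_reset = -60,
    E_ex = 0, E_inh = -80, dt = 1, t_ref = 5, t_ref_inh = 4,
    # conductance kinetics
    tau_AMPA = 40, tau_GABA = 50, exact_decay = FALSE, delay_max = 10,
    g_leak = 8, g_leak_gaba = 3.2,
    # E-STDP
    A_plus = 0.005, beta = 1.05, tau_plus = 20, tau_minus = 20, gE_max = 0.3,
    estdp_pairing = c(w12 = "all", w22ee = "nearest", w22ei = "all",
                      w23 = "all", w33ei = "all"),
    beta_readout = 0.9,
    # I-STDP
    B_plus = 0.0015, B_minus = 0.0003, tau_i = 10, gI_max = 0.2,
    # architecture
    image_size = 30, K = 900, N_E = 200, N_I = 50, M = 8, M_I = 6,
    c12_ee = 0.2, c22_ee = 0.4, c22_ei = 0.4, c22_ie = 0.5, c22_ii = 0.5,
    c23_ee = 0.3, c33_ei = 1, c33_ie = 1,
    # initial weights
    w_init_max_ff = 0.1, w_init_max_ro = 0.2, z_init_max = 0.1,
    # encoder
    f_black = 90, f_noise = 10, noise_fraction = 0.10,
    f_bg = 500, w_bg = 0.1,
    # protocol
    mean_pattern_duration = 30, d_test = 1.4, J = 10, C = 3
  )
  if (preset == "desk") {
    cfg$image_size <- 15; cfg$K <- 225
    cfg$N_E <- 100; cfg$N_I <- 25
    cfg$J <- 5
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(cfg), "A_minus", "A_minus_readout"))
    if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  # depression amplitudes derive from the balance parameters unless overridden
  if (is.null(dots$A_minus))
    cfg$A_minus <- cfg$beta * cfg$A_plus * cfg$tau_plus / cfg$tau_minus
  if (is.null(dots$A_minus_readout))
    cfg$A_minus_readout <- cfg$beta_readout * cfg$A_plus * cfg$tau_plus / cfg$tau_minus
  cfg <- cfg[order(match(names(cfg), names(cfg)))]
  class(cfg) <- "snn_config"
  validate_config(cfg)
  cfg
}

#' @rdname snn_config
#' @param cfg an \code{snn_config} object.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "snn_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in setdiff(names(unclass(cfg)), c("exact_decay", "estdp_pairing")))
    if (!num1(cfg[[f]])) stop("field '", f, "' must be a finite scalar")
  if (!is.logical(cfg$exact_decay)) stop("exact_decay must be logical")
  if (!all(cfg$estdp_pairing %in% c("all", "nearest")))
    stop("estdp_pairing entries must be 'all' or 'nearest'")
  if (cfg$V_reset >= cfg$V_T) stop("V_reset must lie below V_T")
  if (!(cfg$E_inh < cfg$V_rest && cfg$V_rest < cfg$V_T && cfg$V_T < cfg$E_ex))
    stop("reversal potentials must order as E_inh < V_rest < V_T < E_ex")
  for (f in c("tau_m", "tau_AMPA", "tau_GABA", "tau_plus", "tau_minus", "tau_i",
              "dt", "gE_max", "gI_max", "A_plus", "B_plus", "B_minus",
              "mean_pattern_duration", "d_test", "g_leak", "g_leak_gaba"))
    if (cfg[[f]] <= 0) stop("field '", f, "' must be positive")
  if (cfg$t_ref < 0 || cfg$t_ref_inh < 0) stop("refractory periods must be non-negative")
  if (cfg$delay_max < cfg$dt) stop("delay_max must be at least one time step")
    if (cfg[[f]] <= 0) stop("field '", f, "' must be positive")
  for (f in c("c12_ee", "c22_ee", "c22_ei", "c22_ie", "c22_ii", "c23_ee",
              "c33_ei", "c33_ie", "noise_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("connectivity '", f, "' outside [0, 1]")
  for (f in c("K", "N_E", "N_I", "M", "M_I", "J", "C"))
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("field '", f, "' must be a positive integer")
  if (cfg$K != cfg$image_size^2)
    stop("K must equal image_size^2 (one source neuron per pixel)")
  if (cfg$f_black * cfg$dt / 1000 > 1 || cfg$f_noise * cfg$dt / 1000 > 1 ||
      cfg$f_bg * cfg$dt / 1000 > 1)
    stop("f * dt exceeds 1 spike per step")
  if (cfg$f_bg < 0 || cfg$w_bg < 0) stop("background drive must be non-negative")
  invisible(cfg)
}

#' Read or write a configuration as a flat YAML file
#'
#' Every field of \code{\link{snn_config}} maps to one key; missing keys take
#' their preset default.
#'
#' @param cfg an \code{snn_config} object.
#' @param path file path.
#' @param preset preset supplying defaults for keys absent from the file.
#' @return \code{read_config} returns an \code{snn_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "snn_config"))
  vals <- unclass(cfg)
  if (!is.null(names(vals$estdp_pairing)))
    vals$estdp_pairing <- as.list(vals$estdp_pairing)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path, preset = "desk") {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$estdp_pairing)) vals$estdp_pairing <- unlist(vals$estdp_pairing)
  do.call(snn_config, c(list(preset = preset), vals))
}

#' @export
print.snn_config <- function(x, ...) {
  cat("<snn_config>\n")
  cat(sprintf("  layers: K=%d source, %d E + %d I reservoir, %d E + %d I sink\n",
              x$K, x$N_E, x$N_I, x$M, x$M_I))
  cat(sprintf("  LIF: tau_m=%g ms, V_T=%g, V_rest=%g, V_reset=%g mV; dt=%g ms\n",
              x$tau_m, x$V_T, x$V_rest, x$V_reset, x$dt))
  cat(sprintf("  E-STDP: A+=%g, A-=%g (beta=%g), tau=%g/%g ms, gE_max=%g\n",
              x$A_plus, x$A_minus, x$beta, x$tau_plus, x$tau_minus, x$gE_max))
  cat(sprintf("  I-STDP: B+=%g, B-=%g, tau_i=%g ms, gI_max=%g\n",
              x$B_plus, x$B_minus, x$tau_i, x$gI_max))
  cat(sprintf("  encoder: %g Hz black / %g Hz noise on %g%% of white pixels\n",
              x$f_black, x$f_noise, 100 * x$noise_fraction))
  cat(sprintf("  protocol: exp(%g ms) presentations; tests J=%d x d=%g s, C=%d\n",
              x$mean_pattern_duration, x$J, x$d_test, x$C))
  invisible(x)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
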