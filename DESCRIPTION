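Package: spikedisc
Title: Unsupervised Pattern Discrimination in Plastic Spiking Reservoir Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a three-layer spiking reservoir network of
    conductance-based leaky integrate-and-fire neurons with always-on
    excitatory and inhibitory spike-timing-dependent plasticity (STDP).
    Binary images are encoded as Poisson spike trains at a source layer,
    mixed nonlinearly in a recurrent excitatory-inhibitory reservoir, and
    read out by sink neurons whose banded firing-rate vectors form ternary
    codes.  Provides the Discriminability Index (separability times
    uniqueness of readout codes), Fano-factor selection of the test-window
    duration, binarized synaptic-distance diagnostics, receptive-field and
    back-trace graph analysis, and experiment drivers for
    excitation-inhibition balance ablations, connectivity-shuffle controls
    and stability-plasticity protocols.  The millisecond-resolution
    simulation loop is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
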