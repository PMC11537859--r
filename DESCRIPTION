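Package: spikestate
Title: Latent Spiking States of Cortical Populations and Their Relation to
    Brain State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits Poisson-emission hidden Markov models to binned spike
    counts from cortical population recordings and relates the inferred
    latent spiking states to classical measures of brain state.  Provides
    forward-backward posterior decoding, Baum-Welch estimation with
    train/test splitting by recording segment, simulation and shuffle
    controls for model fit quality, Bhattacharyya overlap between states,
    an LFP band-ratio (LF/HF) state metric, balanced linear max-margin
    decoding of LFP state from spiking features, shuffle tests for
    state-dependent sensory-evoked responses, whisking-onset detection,
    and mutual information between spiking states and whisking behavior.
    Includes a synthetic-recording generator with known ground truth for
    end-to-end validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
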