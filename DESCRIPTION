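Package: stspwm
Title: Working-Memory Recurrent Networks with Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recurrent neural network models of object working memory with and
    without short-term synaptic plasticity (STSP), trained by
    backpropagation-through-time on a distracted delayed-match-to-sample task.
    Implements fixed-synapse rate networks (tanh and rectifier), a
    presynaptic facilitation/depression model with Dale's-law constrained
    weights, and an anti-Hebbian plastic-weight network, together with the
    population-analysis stack used to compare them to cortical recordings:
    Gaussian-kernel rate smoothing, time-resolved cross-validated decoding,
    neural trajectory distance statistics with multi-level bootstrap
    confidence intervals, exponential recovery-time-constant fitting,
    synaptic-ablation and process-noise robustness scores, LDA state-space
    projection with orthogonal Procrustes alignment, and a surrogate
    multi-session spiking-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    e1071,
    MASS,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
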