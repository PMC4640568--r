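Package: spikeswitch
Title: Single-Trial State-Switch Analysis of Trial-Aligned Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify, in trial-aligned single-neuron recordings
    from a two-alternative forced-choice task, neurons whose firing rates
    encode movement time or decision difficulty, and to classify
    difficulty-encoding neurons into switch-time, rate, and binary coding
    mechanisms. Implements sliding-window firing-rate estimation,
    bin-wise linear models with Monte-Carlo permutation nulls and a
    consecutive-significant-bin run-length criterion under
    Benjamini-Hochberg false-discovery-rate control, two-state
    Bernoulli-emission hidden Markov models fitted by Baum-Welch with
    Viterbi decoding of single-trial switch times, Kendall correlation
    tests of switch timing and post-switch rate against difficulty, and an
    equal-weight two-Gaussian mixture versus single-Gaussian comparison by
    the Bayesian Information Criterion with a Monte-Carlo null. A
    synthetic-session generator with known ground truth (psychometric
    choices, X-patterned movement times, inhomogeneous Poisson spike
    trains from each coding mechanism) supports validation of the whole
    chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
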