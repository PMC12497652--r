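Package: tinda
Title: Temporal Interval Network Density Analysis of Discrete Brain-State Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies directed, cyclical structure in discrete network-state
    time courses such as hidden Markov model state paths inferred from
    electrophysiology. For every reference state the variable-length intervals
    between its reactivations are split evenly in half and the fractional
    occupancy of every other state is contrasted between the two halves,
    yielding a K x K fractional-occupancy asymmetry matrix per subject.
    Downstream tools arrange states on the unit circle, score the net
    rotational flow (cycle strength), optimize the ordering, run label-shuffle
    permutation inference, characterize the dependence of the cycle on
    interval duration via percentile binning, and estimate cycle duration and
    rate with a constrained sequential four-metastate Poisson decoder. A
    semi-Markov simulator with controllable rotational bias and heavy-tailed
    dwell times makes every stage verifiable without access to restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    igraph,
    clue
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
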