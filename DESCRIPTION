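Package: repliscape
Title: Stochastic Modelling of Human Genome Replication and Inference of
    Initiation Probability Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-genome DNA replication kinetics with a limiting,
    progressively activated pool of firing factors acting on an initiation
    probability landscape (IPLS) over a 5 kb binned genome.  Computes the
    population observables measured by Repli-seq and OK-seq experiments
    (mean replication timing, replication fork directionality, origin
    efficiency, S-phase duration quantiles, time-dependent firing rate),
    cross-validates MRT against RFD through the constant-fork-speed
    relation, derives closed-form estimators of potential origin density
    from RFD upshifts and MRT, and inverts MRT + RFD profiles into an IPLS
    with an iterative convolutional-network procedure.  Includes a
    synthetic landscape generator so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
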