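Package: ColE2sim
Title: Hierarchical Post-Transcriptional Regulation and Lysis Dynamics of
    the Colicin E2 Operon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of the colicin E2
    expression network in Escherichia coli. Implements the reduced
    three-component titration motif (long mRNA, CsrA dimers, an effective
    sRNA with coupled degradation), its exact and approximate stationary
    solutions and expression threshold, van Kampen linear-noise analysis of
    long-mRNA fluctuations (Fano factors), an exact Gillespie stochastic
    simulation engine for the reduced, detailed multi-site, and full
    SOS-coupled reaction schemes, and a LexA-RecA SOS response module
    producing first-peak (lysis) time distributions and survival curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
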