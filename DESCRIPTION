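Package: pilusgrowth
Title: Stochastic Kinetics of P-Pilus Assembly from Pairwise
    Donor-Strand-Exchange Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the growth of the Escherichia coli P pilus as an
    absorbing Markov chain over the six Pap pilin subunits, driven by
    pairwise pseudo-first-order donor-strand-exchange (DSE) rates and
    relative subunit concentrations.  Provides exact log-space length and
    correct-sequence probability distributions, closed-form tail
    probabilities of long correctly ordered pili, kinetic Monte Carlo
    simulation of pilus ensembles with exponential waiting times,
    exponential-decay fitting with log-space extrapolation, conditional
    assembly-time estimation, scenario sweeps over rate ratios and
    concentration fold-changes, and generators for synthetic rate tables
    with a cognate-fast/non-cognate-slow structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
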