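Package: ionextract
Title: Selected Ion Extraction of Peptide Delta-Mass Peaks for Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the precursor delta-mass distribution of
    peptide-spectrum matches from wide-window (-3 to +5 Da) tandem
    mass-spectrometry searches of human plasma. Implements in-silico tryptic
    digestion and isotopic-envelope computation, a synthetic LC-MS/MS run
    generator with heavy-isotope and hydrogen-loss precursor sampling, a
    calibrated random-spectrum Monte-Carlo control, a simplified
    goodness-of-fit peptide-spectrum matcher, Gaussian density analysis and
    integer-peak detection of delta masses, selected-ion extraction under
    configurable window sets, observation-frequency correction against blank
    and random controls (chi-square), Benjamini-Hochberg q-values, and
    type I / type II error reporting across extraction treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
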