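Package: condquant
Title: Quantification of Optogenetic mRNA Condensates in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("condquant", "developers", role = c("aut", "cre"),
    email = "maintainers@condquant.dev")
Description: An end-to-end toolkit for quantifying light-activated biomolecular
    condensates and their interactions with single mRNA molecules in
    fluorescence microscopy data. Provides synthetic scene generators with
    known ground truth (smFISH z-stacks, two-colour live movies, FRAP traces,
    translation-reporter time courses, per-cell expression scans and
    dendritic-spine stacks), preprocessing (flat-field, rolling-ball
    background, band-pass, bleach, drift and channel-registration
    corrections), condensate segmentation and sub-pixel spot localization,
    recruitment-fraction statistics, single-particle tracking with mean
    squared displacement and binding-event analysis, saturation-concentration
    estimation and a Flory-Huggins ternary regular-solution coexistence
    calculator, plus FRAP, reporter-decay, spine-volume and nascent-protein
    readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
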