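Package: branchedub
Title: Branched Ubiquitin Chain Architectures, Mass-Tagged DUB Assays and
    Pulldown Binder Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with branched, mixed and homotypic
    polyubiquitin chain architectures. Provides a formal ASCII nomenclature
    for chain topologies with a parser, canonical formatter and topology
    classifier; an average/monoisotopic mass engine for designing
    mass-distinguishable (mass-tagged) substrate chains including uniform
    15N labelling; a MALDI-TOF quantification pipeline for deubiquitinase
    linkage-specificity assays (Savitzky-Golay smoothing, top-hat baseline
    subtraction, S/N-thresholded peak detection, internal single-point
    calibration against a 15N-ubiquitin standard, and percent-linkage-cleaved
    quantification with panel normalization); seeded synthetic-data
    generators for reflectron-mode spectra, deubiquitinase reactions and
    quadruplicate pulldown intensity matrices; and the pulldown
    binder-profiling statistics (unique-peptide filtering, median
    normalization, left-censored Gaussian imputation, per-protein one-way
    ANOVA with Benjamini-Hochberg control, Z-scoring and Euclidean
    hierarchical clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mclust,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
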