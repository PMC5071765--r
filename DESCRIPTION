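Package: cdomics
Title: Integrated NMR Metabolomics and iTRAQ Proteomics Analysis of
    Cadmium Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for characterizing heavy-metal stress
    responses from paired 1H-NMR metabolomics and iTRAQ proteomics data,
    as used in aquatic ecotoxicology of filter-feeding bivalves. Covers
    spectral binning with water-region exclusion, total-area
    normalization and generalized-log variance stabilization; NIPALS
    PLS-DA and OPLS-DA with venetian-blind cross-validated Q2, CV-ANOVA
    and correlation-coefficient biomarker calling; replicate-ratio
    fold-change filtering of isobaric-tag protein quantification;
    best-homolog mapping and hypergeometric term enrichment; and
    shortest-path bridging of differentially expressed proteins to
    pathway and metabolite nodes in a scored interactome, yielding a
    Cytoscape-compatible regulation network. A synthetic-data module
    generates spectra, protein tables, homology hits, annotation sets
    and interactomes with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
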