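Package: stimspace
Title: Spatial Transcriptomics Analysis of Tissue Responses Around
    Stimulating Cortical Microelectrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spot-level spatial transcriptomics analysis of the
    tissue response around implanted, electrically stimulated cortical
    microelectrodes. Provides a Visium-style synthetic data generator with
    known ground truth, readers and writers for the SpaceRanger on-disk
    dialect, sequencing-depth equalization by binomial count thinning,
    per-spot size-factor normalization, cluster-versus-cluster differential
    expression with a negative-binomial exact test, implant-site
    localization from marker genes plus a stereotaxic prior, radial
    distance-binned expression profiles, fluorescence IHC quantification
    (NeuN+ nuclei density and within-section normalized GFAP intensity),
    hypergeometric gene-set over-representation analysis, and
    charge/charge-density stimulation-safety arithmetic (Shannon limits,
    4 nC rule).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    pracma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
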