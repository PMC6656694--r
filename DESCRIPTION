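Package: CytoMonitor
Title: Standardized Mass-Cytometry Immune Monitoring from Raw Events to
    Differential Abundance
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, end-to-end workflow for mass-cytometry (CyTOF)
    immune monitoring built around a 33-antibody reference panel: bead-based
    correction of acquisition-time sensitivity drift, palladium-barcode
    sample deconvolution, arcsinh/percentile transforms, automated
    pre-gating and hierarchical gating of the major immune lineages,
    self-organizing-map clustering with automatic lineage annotation and
    within-lineage subclustering, panel-coverage and cross-run
    reproducibility QC, and negative-binomial differential abundance of
    population counts between clinical groups. A synthetic-data generator
    emulating PBMC and bone-marrow-transplant cohorts (multimodal arcsinh
    marker distributions, calibration beads, sensitivity drift, dead cells,
    doublets, barcodes) provides ground truth so every stage is testable
    without instrument data. Reads and writes FCS 3.0/3.1 files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: FlowCytometry, SingleCell, Clustering, Proteomics, QualityControl
RoxygenNote: 7.3.3
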