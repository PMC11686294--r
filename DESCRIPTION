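Package: SortScape
Title: Sort-Seq Regulatory Landscape Topography and Adaptive Walks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to turn sort-seq (FACS bin-sorted, sequenced) read counts
    for a transcription-factor binding-site library into a quantitative
    repression landscape, and to characterise that landscape's topography and
    navigability. Implements weighted-bin expression and repression scoring
    with replicate filtering, genotype (Hamming) network construction with
    noise-aware uphill-edge orientation, peak/plateau detection, shuffled null
    landscapes, basins of attraction, accessible-path census, sign-epistasis
    classification on mutational squares, one-hot PCA, and adaptive-walk
    simulation (greedy, uniform SSWM, Kimura fixation with drift). A
    synthetic-data module generates ground-truth landscapes (additive, NK,
    House-of-Cards) and simulated sort-seq count tables so the full pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Regression, GeneRegulation, NetworkInference
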