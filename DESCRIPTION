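Package: hemodyn
Title: Integrative Chromatin, Accessibility and Transcription Factor
    Dynamics Across Hematopoietic Specification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the integrative analysis of staged multi-omics data
    from in vitro hematopoietic specification (ESC, mesoderm, hemangioblast,
    hemogenic endothelium, hematopoietic progenitor, macrophage): chromatin
    state segmentation with a multivariate hidden Markov model over binarized
    DNaseI accessibility and histone marks, coarse graining to a four-state
    promoter model, six-digit binary encoding of DNaseI hypersensitive site
    dynamics, region-size-aware overlap significance between transcription
    factor binding and gene or DHS sets, position-weight-matrix motif scanning
    with bootstrap relative-enrichment statistics, and stage-resolved core
    gene regulatory network assembly. Includes a synthetic six-stage data
    generator with a planted-truth manifest so every step of the pipeline can
    be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
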