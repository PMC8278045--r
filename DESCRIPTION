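Package: PulldownAssoc
Title: Quantifying Protein Supercomplex Association from Bait-Tagged
    Pull-Down Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of GFP pull-down (co-immunoprecipitation)
    label-free mass-spectrometry data for estimating which multi-subunit
    membrane complexes associate into supercomplexes and which subunits sit
    at the complex-complex interfaces. Provides bait (GFP) normalization,
    complex-level quantification by subunit summation, cross-pulldown
    association-fraction estimation with replicate statistics, one-vs-rest
    interface-subunit tests, pulldown-versus-wild-type volcano enrichment
    analysis, a forward simulator of the pull-down observation model for
    validation by parameter recovery, and a compact atomic force microscopy
    cross-section morphometry module (particle heights and vertex
    distances).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization, Software
RoxygenNote: 7.3.3
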