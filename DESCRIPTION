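Package: specerror
Title: Multivariate Measurement-Error Analysis for Replicated NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise multivariate measurement error in
    replicated spectra from miniaturized near-infrared (NIR) instruments.
    Provides a design-annotated spectra container built on
    SummarizedExperiment, ANOVA-simultaneous component analysis (ASCA)
    with permutation significance testing, replicate-based estimation of
    error covariance and correlation matrices with session pooling, the
    eigenvalue-based K redundancy index with its dimension-dependent
    imbedded minimum, image-histogram summaries of error-correlation
    structure, standard spectral preprocessing (SNV, MSC,
    Savitzky-Golay derivatives), and a full-factorial synthetic spectra
    generator for validating every stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
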