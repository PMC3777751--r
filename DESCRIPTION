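Package: aslcbf
Title: Pulsed Arterial Spin Labeling Perfusion Quantification, Cleaning and
    Group Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pulsed arterial spin labeling (PASL)
    perfusion MRI in neurodegeneration studies: simulation of digital
    perfusion phantoms and cohorts, denoising (motion correction, spatial
    smoothing, temporal high-pass filtering, nuisance regression), pairwise
    subtraction and one-compartment QUIPSS-II cerebral blood flow (CBF)
    quantification, adaptive correlation-based outlier cleaning of the CBF
    time series, partial volume correction, spherical meta-ROI summarization,
    hippocampal volume normalization, and the group-level statistical
    battery (dummy-coded group regression with planned contrasts, partial
    correlations, and hierarchical stepwise regression of disease severity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
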