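Package: maldiscreen
Title: Serum Peptidome Profiling and Biomarker Screening for MALDI-TOF
    Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end re-usable pipeline for low-molecular-weight
    serum peptidome biomarker discovery from MALDI-TOF mass spectra:
    stationary-wavelet (UDWT) denoising, moving-minimum baseline removal,
    low-mass cropping and total-ion-current normalization; per-sample peak
    detection with local signal-to-noise filtering; cross-sample peak
    clustering at fractional m/z tolerance with a prevalence filter;
    Wilcoxon rank-sum feature screening; genetic-algorithm-wrapped SVM
    (radial kernel) classification with leave-one-out cross-validation and
    Youden-index marker ranking; and candidate-protein matching by average
    molecular weight and isoelectric point against a peptide-hormone
    database. A synthetic-cohort generator reproduces the statistical
    structure of a two-group osteopenia study (discriminating peaks at
    1699 and 3038 Da) so the whole pipeline is testable without access to
    the original serum spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
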