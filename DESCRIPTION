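Package: AgiPipe
Title: Processing, Normalisation and Quality Control of Agilent
    Two-Colour Expression Arrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for two-colour long-oligonucleotide expression
    arrays scanned with Agilent Feature Extraction software. Parses the
    tab-delimited scanner output, collapses replicate probes, log2
    transforms the median signals, and normalises every array against
    the per-probe mean of all arrays by global linear regression,
    segmented locally-linear (LOESS) regression, or quantile
    normalisation. Provides the accompanying quality-control statistics
    (signal-dependence of the standard deviation, per-probe normality
    screening, genewise standard deviations, between-channel covariance
    and the covariance-corrected standard deviation of the log-ratio),
    expressed/not-expressed calling against a negative-control
    background probe, and classical multidimensional scaling with a
    cumulative eigenvalue goodness-of-fit statistic for choosing the
    number of dimensions. A synthetic scanner-file generator with known
    truth makes the whole pipeline testable without physical arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    limma,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
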