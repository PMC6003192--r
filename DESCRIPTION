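Package: earpheno
Title: Maize Ear and Kernel Phenotyping from Plot-Level Digital Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts maize yield-component traits from nadir photographs of
    de-husked ears laid on a dark background. Implements the ear digital
    imaging workflow: pixel subtraction, contrast-limited adaptive histogram
    equalization, unsharp masking, Phansalkar local thresholding,
    tolerance-based watershed splitting and particle analysis; linear
    calibrations that turn visible kernel counts and mean kernel length into
    total kernel number and kernel weight; and the trait-reliability and
    genetics statistics used to validate such pipelines (Lin's concordance
    correlation, RMSE, variance components, broad-sense heritability, genetic
    correlation). A deterministic synthetic-image generator renders ear and
    kernel fixtures with exact ground truth for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
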